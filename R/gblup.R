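#' Fixed-effect design matrix with QTL-marker covariates
#'
#' Builds the X matrix of the prediction model: an intercept plus one
#' minor-allele dosage column per covariate marker (model 1 is the empty
#' covariate set, so X is the intercept only). Rank-deficient columns are
#' detected by pivoted QR (tolerance 1e-8), removed, and recorded in the
#' `"dropped"` attribute.
#'
#' @param geno a complete [geno_matrix()] (covariate markers must be imputed).
#' @param markers character vector of covariate marker ids (may be empty).
#' @param lines line ids defining the rows.
#' @param drop_aliased drop rank-deficient columns (set to `FALSE` when
#'   building prediction rows, where the retained training columns are
#'   selected instead).
#' @return numeric matrix with attribute `dropped` (removed column names).
#' @export
build_fixed_design <- function(geno, markers = character(0), lines,
                               drop_aliased = TRUE) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (length(lines) == 0L) stop("zero lines in design")
  absent <- setdiff(lines, rownames(geno$dosage))
  if (length(absent)) stop("unknown line id(s): ",
                           paste(utils::head(absent, 5), collapse = ", "))
  bad <- setdiff(markers, colnames(geno$dosage))
  if (length(bad)) stop("covariate marker(s) absent from panel: ",
                        paste(bad, collapse = ", "))
  X <- cbind(`(Intercept)` = rep(1, length(lines)))
  rownames(X) <- lines
  if (length(markers)) {
    M <- geno$dosage[lines, markers, drop = FALSE]
    if (anyNA(M)) stop("covariate markers contain missing calls; impute first")
    X <- cbind(X, M)
  }
  if (drop_aliased) {
    qrX <- qr(X, tol = 1e-8)
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    X <- X[, keep, drop = FALSE]
    attr(X, "dropped") <- dropped
  } else {
    attr(X, "dropped") <- character(0)
  }
  X
}

#' Covariate marker sets for the prediction model variants
#'
#' @param panel the `panel` data.frame of a [qtl_architecture()] (columns
#'   marker, qtl, role) or a user table of the same shape.
#' @param variant one of `"model1"` (mean only), `"model2_qtl17"` (the full
#'   sprouting QTL panel), `"model2_phs"` (the three major-locus markers) or
#'   `"model2_rht"` (the T1RS.1BL / Rht-B1 / Rht-D1 markers).
#' @return character vector of covariate marker ids.
#' @export
variant_covariates <- function(panel, variant = c("model1", "model2_qtl17",
                                                  "model2_phs", "model2_rht")) {
  variant <- match.arg(variant)
  switch(variant,
         model1 = character(0),
         model2_qtl17 = panel$marker[panel$role == "phs"],
         model2_phs = panel$marker[panel$qtl == "PhsA1_4A"],
         model2_rht = panel$marker[panel$role == "fn"])
}

# profile restricted log-likelihood at variance ratio lambda = s2t/s2e,
# in the eigenbasis of K: yt = U'y, Xt = U'X, d = eigenvalues
reml_profile <- function(log10_lambda, d, yt, Xt) {
  lambda <- 10^log10_lambda
  w <- lambda * d + 1
  n <- length(yt); p <- ncol(Xt)
  Xw <- Xt / w
  XtWX <- crossprod(Xt, Xw)
  XtWy <- crossprod(Xw, yt)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  r <- yt - Xt %*% beta
  rss <- sum(r^2 / w)
  s2e <- rss / (n - p)
  if (!is.finite(s2e) || s2e <= 0) return(list(ll = -Inf))
  ll <- -0.5 * ((n - p) * log(2 * pi * s2e) + sum(log(w)) +
                  2 * sum(log(diag(ch))) + (n - p))
  list(ll = ll, beta = as.numeric(beta), s2e = s2e, lambda = lambda, w = w)
}

#' Genomic BLUP with REML variance components
#'
#' Fits the mixed model \deqn{y = X\beta + t + e,\quad t \sim N(0, A
#' \sigma^2_t),\quad e \sim N(0, I \sigma^2_e)} to line-level adjusted means,
#' with A a genomic relationship matrix ([vanraden_grm()]). Restricted
#' maximum likelihood is computed in the eigenbasis of A: the covariance is
#' diagonal there, the likelihood is profiled analytically over \eqn{\beta}
#' and \eqn{\sigma^2_e}, and the variance ratio \eqn{\lambda =
#' \sigma^2_t/\sigma^2_e} is maximized by a grid-bracketed Brent search on
#' \eqn{\log_{10}\lambda} over `lambda_bounds`. If the smallest eigenvalue of
#' A is below 1e-8 a ridge of `ridge` is added to the diagonal (recorded in
#' the fit).
#'
#' @param y named numeric vector of phenotypes (adjusted means), one per line.
#' @param K relationship matrix covering at least the lines of `y`.
#' @param X fixed-effect design matrix (default: intercept only), rows
#'   matching `y`; see [build_fixed_design()].
#' @param lambda_bounds search bounds for the variance ratio.
#' @param ridge diagonal ridge applied when A is numerically singular.
#' @return an object of class `gblup` with components `beta` (fixed
#'   effects), `u` (breeding values of the training lines), `sigma2_t`,
#'   `sigma2_e`, `logLik` (maximized restricted log-likelihood), `fitted`,
#'   `residuals`, and bookkeeping (`dropped`, `ridge_applied`, `converged`).
#' @export
gblup <- function(y, K, X = NULL, lambda_bounds = c(1e-6, 1e6),
                  ridge = 1e-6) {
  stopifnot(is.numeric(y), !is.null(names(y)))
  ids <- names(y)
  if (!all(ids %in% rownames(K)))
    stop("K does not cover all phenotyped lines")
  A <- unclass(K)[ids, ids, drop = FALSE]
  n <- length(y)
  if (is.null(X)) {
    X <- matrix(1, n, 1, dimnames = list(ids, "(Intercept)"))
  }
  stopifnot(nrow(X) == n)
  if (!is.null(rownames(X)) && !identical(rownames(X), ids))
    X <- X[ids, , drop = FALSE]
  p <- ncol(X)
  if (p == 0L) stop("X has rank 0")
  if (n <= p) stop("more fixed effects than observations")
  if (qr(X, tol = 1e-8)$rank < p)
    stop("X is rank deficient; use build_fixed_design() to drop aliased columns")

  eg <- eigen(A, symmetric = TRUE)
  ridge_applied <- FALSE
  d <- eg$values
  if (min(d) < -1e-8) {
    # substantially negative eigenvalues: A is not PSD, regularize and log
    d <- d + ridge
    ridge_applied <- TRUE
  }
  d <- pmax(d, 0)
  U <- eg$vectors
  yt <- as.numeric(crossprod(U, y))
  Xt <- crossprod(U, X)

  lb <- log10(lambda_bounds)
  grid <- seq(lb[1], lb[2], length.out = 41)
  ll_grid <- vapply(grid, function(g) reml_profile(g, d, yt, Xt)$ll, 0)
  i0 <- which.max(ll_grid)
  lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
  opt <- suppressWarnings(
    stats::optimize(function(g) reml_profile(g, d, yt, Xt)$ll,
                    c(lo, hi), maximum = TRUE, tol = 1e-10))
  # keep the grid point if the local search somehow lost it
  if (opt$objective < ll_grid[i0]) {
    opt <- list(maximum = grid[i0], objective = ll_grid[i0])
  }
  prof <- reml_profile(opt$maximum, d, yt, Xt)
  if (!is.finite(prof$ll) || is.null(prof$beta)) {
    # degenerate data (e.g. zero residual variation): fall back to OLS,
    # zero genetic variance, and flag non-convergence
    beta_ols <- qr.coef(qr(X), y)
    fit_ols <- as.numeric(X %*% beta_ols)
    return(structure(list(
      beta = stats::setNames(beta_ols, colnames(X)),
      u = stats::setNames(rep(0, n), ids),
      sigma2_t = 0, sigma2_e = stats::var(y - fit_ols), lambda = 0,
      logLik = NA_real_, fitted = stats::setNames(fit_ols, ids),
      residuals = y - fit_ols, y = y,
      vinv_r = rep(0, n), train_ids = ids,
      dropped = attr(X, "dropped") %||% character(0),
      ridge = if (ridge_applied) ridge else 0, ridge_applied = ridge_applied,
      converged = FALSE, at_bound = FALSE, n = n, p = p),
      class = "gblup"))
  }
  lambda <- prof$lambda
  s2e <- prof$s2e
  s2t <- lambda * s2e
  beta <- stats::setNames(prof$beta, colnames(X))

  r_t <- yt - Xt %*% prof$beta
  # t_hat = s2t * A %*% V^-1 r ; in the eigenbasis V = s2e * diag(w) and
  # the effective (possibly ridged) A is diag(d)
  vinv_r <- U %*% (r_t / (s2e * prof$w))
  u <- as.numeric(U %*% (s2t * d * r_t / (s2e * prof$w)))
  names(u) <- ids
  fitted <- as.numeric(X %*% prof$beta) + u
  names(fitted) <- ids

  structure(list(beta = beta, u = u, sigma2_t = s2t, sigma2_e = s2e,
                 lambda = lambda, logLik = prof$ll,
                 fitted = fitted, residuals = y - fitted, y = y,
                 vinv_r = as.numeric(vinv_r), train_ids = ids,
                 dropped = attr(X, "dropped") %||% character(0),
                 ridge = if (ridge_applied) ridge else 0,
                 ridge_applied = ridge_applied,
                 converged = is.finite(prof$ll),
                 at_bound = opt$maximum <= lb[1] + 1e-8 ||
                   opt$maximum >= lb[2] - 1e-8,
                 n = n, p = p),
            class = "gblup")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gblup <- function(x, ...) {
  cat("GBLUP fit (REML)\n")
  cat(sprintf("  n = %d lines, %d fixed effect(s)%s\n", x$n, x$p,
              if (length(x$dropped))
                paste0(" (dropped aliased: ",
                       paste(x$dropped, collapse = ", "), ")") else ""))
  cat(sprintf("  sigma2_t = %.4f, sigma2_e = %.4f (lambda = %.4g)\n",
              x$sigma2_t, x$sigma2_e, x$lambda))
  cat(sprintf("  restricted logLik = %.3f%s\n", x$logLik,
              if (x$ridge_applied) sprintf(" [ridge %.1g on diag(A)]", x$ridge)
              else ""))
  invisible(x)
}

#' @export
summary.gblup <- function(object, ...) {
  h2 <- object$sigma2_t / (object$sigma2_t + object$sigma2_e)
  structure(list(fit = object, genomic_h2 = h2,
                 beta = object$beta,
                 u_range = range(object$u)),
            class = "summary.gblup")
}

#' @export
print.summary.gblup <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  genomic h2 = sigma2_t / (sigma2_t + sigma2_e) = %.3f\n",
              x$genomic_h2))
  cat("  fixed effects:\n")
  print(round(x$beta, 4))
  cat(sprintf("  breeding values in [%.3f, %.3f]\n",
              x$u_range[1], x$u_range[2]))
  invisible(x)
}

#' @export
coef.gblup <- function(object, ...) object$beta

#' @export
fitted.gblup <- function(object, ...) object$fitted

#' @export
residuals.gblup <- function(object, ...) object$residuals

#' @export
logLik.gblup <- function(object, ...) {
  structure(object$logLik, df = object$p + 2, nobs = object$n,
            class = "logLik")
}

#' Predict breeding values of unphenotyped lines
#'
#' The genomic part of a target line's prediction is the conditional
#' expectation of its breeding value given the training phenotypes,
#' \eqn{\hat t_{new} = \sigma^2_t K_{new,train} V^{-1} (y - X\hat\beta)}
#' (equivalently \eqn{A_{cross} A_{train}^{-1} \hat t_{train}}); the fixed
#' part is \eqn{X_{new} \hat\beta}. The total GEBV is their sum.
#'
#' @param object a [gblup()] fit.
#' @param K the full relationship matrix (must cover training and target
#'   lines; the same matrix the model was fitted from).
#' @param lines target line ids (default: all lines of `K` not in training).
#' @param X_new fixed-effect design matrix for the target lines; defaults to
#'   an intercept column, which is only valid for an intercept-only fit.
#' @param geno optional [geno_matrix()] from which `X_new` is rebuilt with
#'   the same covariate columns as the training design.
#' @param ... ignored.
#' @return data.frame with columns line, fixed, genomic, gebv.
#' @export
predict.gblup <- function(object, K, lines = NULL, X_new = NULL, geno = NULL,
                          ...) {
  if (is.null(lines))
    lines <- setdiff(rownames(K), object$train_ids)
  if (!length(lines)) stop("no target lines")
  if (!all(lines %in% rownames(K)))
    stop("K does not cover all target lines")
  K_cross <- unclass(K)[lines, object$train_ids, drop = FALSE]
  genomic <- as.numeric(object$sigma2_t * (K_cross %*% object$vinv_r))
  if (is.null(X_new)) {
    if (!is.null(geno)) {
      covs <- setdiff(names(object$beta), "(Intercept)")
      X_new <- cbind(`(Intercept)` = rep(1, length(lines)),
                     if (length(covs)) geno$dosage[lines, covs, drop = FALSE])
    } else {
      if (length(object$beta) > 1L)
        stop("fit has marker covariates: supply X_new or geno")
      X_new <- matrix(1, length(lines), 1)
    }
  }
  stopifnot(nrow(X_new) == length(lines), ncol(X_new) == length(object$beta))
  fixed <- as.numeric(X_new %*% object$beta)
  data.frame(line = lines, fixed = fixed, genomic = genomic,
             gebv = fixed + genomic, stringsAsFactors = FALSE)
}

#' GEBVs of the training lines
#'
#' The paper-style genome-estimated breeding value of a phenotyped line is
#' its fixed part plus its BLUP, i.e. the fitted value of the model.
#'
#' @param object a [gblup()] fit.
#' @return named numeric vector.
#' @export
gebv <- function(object) {
  stopifnot(inherits(object, "gblup"))
  object$fitted
}
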