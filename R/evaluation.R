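#' Program-stratified cross-validation folds
#'
#' Builds the replicated fold plan of the within-season scheme: in each of
#' `reps` replicates, the lines of every breeding program are randomly split
#' into `k` sets of (nearly) equal size, so each estimation and test set
#' contains lines from every program and each line is used exactly once per
#' replicate as a test line.
#'
#' @param lines data.frame with columns `line` and `program`, or a
#'   [geno_matrix()] (its line metadata is used).
#' @param k folds per replicate (default 5).
#' @param reps replicates (default 10).
#' @param seed integer seed.
#' @return a `fold_plan`: data.frame (rep, line, program, fold) with
#'   attributes k, reps, seed.
#' @export
make_folds <- function(lines, k = 5L, reps = 10L, seed = 1L) {
  if (inherits(lines, "geno_matrix")) lines <- lines$lines
  stopifnot(all(c("line", "program") %in% names(lines)))
  if (anyNA(lines$program)) stop("every line needs a program label")
  small <- table(lines$program)
  small <- names(small)[small < k]
  if (length(small))
    message("program(s) with fewer than k lines (some folds get none): ",
            paste(small, collapse = ", "))
  out <- with_seed(seed, {
    plans <- vector("list", reps)
    for (r in seq_len(reps)) {
      fold <- integer(nrow(lines))
      for (pr in unique(lines$program)) {
        idx <- which(lines$program == pr)
        # balanced labels, remainder folds chosen at random, lines shuffled
        labels <- sample(k)[rep_len(seq_len(k), length(idx))]
        fold[idx[sample(length(idx))]] <- labels
      }
      plans[[r]] <- data.frame(rep = r, line = lines$line,
                               program = lines$program, fold = fold,
                               stringsAsFactors = FALSE)
    }
    do.call(rbind, plans)
  })
  structure(out, k = as.integer(k), reps = as.integer(reps),
            seed = as.integer(seed), class = c("fold_plan", "data.frame"))
}

plan_signature <- function(plan) {
  paste(plan$rep, plan$line, plan$fold, sep = "|", collapse = ";")
}

#' Cross-validated predictive ability
#'
#' Runs the full stratified CV: for every (replicate, fold) pair the model is
#' refitted on the estimation set (variance components re-estimated per
#' fold), the test-set GEBVs are predicted, and the predictive ability is the
#' Pearson correlation between predicted and observed breeding values,
#' \eqn{r(y_{TS}, \hat g_{TS})}. Reusing one fold plan across model variants
#' pairs the runs for [compare_models()].
#'
#' @param means named numeric vector of adjusted means (the observed breeding
#'   values).
#' @param K relationship matrix covering the lines.
#' @param plan a [make_folds()] plan over the lines of `means`.
#' @param geno a complete [geno_matrix()]; needed whenever `covariates` is
#'   non-empty.
#' @param covariates covariate marker ids (see [variant_covariates()]);
#'   empty for model 1.
#' @param model label stored with the result.
#' @return a `cv_result`: data.frame (rep, fold, n_ts, r) with the plan
#'   signature attached; `r` is `NA` (excluded from means, with a message)
#'   when the correlation is undefined.
#' @export
cross_validate <- function(means, K, plan, geno = NULL,
                           covariates = character(0), model = "model1") {
  stopifnot(inherits(plan, "fold_plan"))
  ids <- names(means)
  miss <- setdiff(unique(plan$line), ids)
  if (length(miss))
    stop("adjusted means missing for plan line(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  if (length(covariates) && is.null(geno))
    stop("covariates given but no geno supplied")
  out <- list()
  for (r in unique(plan$rep)) {
    pr <- plan[plan$rep == r, , drop = FALSE]
    for (f in sort(unique(pr$fold))) {
      ts <- intersect(pr$line[pr$fold == f], ids)
      es <- intersect(pr$line[pr$fold != f], ids)
      X <- build_fixed_design(geno %||% NULL_geno(es), covariates, es)
      fit <- gblup(means[es], K, X = X)
      pred <- predict(fit, K, lines = ts,
                      X_new = build_fixed_design(geno %||% NULL_geno(ts),
                                                 covariates, ts,
                                                 drop_aliased = FALSE)[,
                        names(fit$beta), drop = FALSE])
      obs <- means[ts]
      sd_p <- stats::sd(pred$gebv); sd_o <- stats::sd(obs)
      rr <- if (length(ts) < 2 || is.na(sd_p) || is.na(sd_o) ||
                sd_p == 0 || sd_o == 0) {
        message(sprintf("rep %d fold %d: constant predictions or phenotypes; r undefined", r, f))
        NA_real_
      } else stats::cor(obs, pred$gebv)
      out[[length(out) + 1L]] <- data.frame(rep = r, fold = f,
                                            n_ts = length(ts), r = rr)
    }
  }
  res <- do.call(rbind, out)
  structure(res, model = model, plan_signature = plan_signature(plan),
            class = c("cv_result", "data.frame"))
}

# intercept-only stand-in so build_fixed_design can run without genotypes
NULL_geno <- function(lines) {
  geno_matrix(matrix(0, length(lines), 1,
                     dimnames = list(lines, "M_dummy")))
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Cross-validation result [%s]: %d runs, mean r = %.3f (sd %.3f)\n",
              attr(x, "model"), nrow(x), mean(x$r, na.rm = TRUE),
              stats::sd(x$r, na.rm = TRUE)))
  if (anyNA(x$r)) cat("  (", sum(is.na(x$r)), "undefined runs excluded )\n")
  invisible(x)
}

#' @export
mean.cv_result <- function(x, ...) mean(x$r, na.rm = TRUE)

#' Paired comparison of two prediction models
#'
#' Student's paired t-test over the per-run predictive-ability differences of
#' two [cross_validate()] results that share the same fold plan (pairing
#' unit: replicate x fold). Significance codes follow the usual convention
#' (ns, *, **, *** at 0.05 / 0.01 / 0.001).
#'
#' @param a,b `cv_result` objects with identical fold plans.
#' @return list (class `model_comparison`) with mean_a, mean_b, mean_diff
#'   (a - b), t, df, p_value, stars.
#' @export
compare_models <- function(a, b) {
  stopifnot(inherits(a, "cv_result"), inherits(b, "cv_result"))
  if (!identical(attr(a, "plan_signature"), attr(b, "plan_signature")))
    stop("cv_results were not computed on the same fold plan")
  m <- merge(as.data.frame(a), as.data.frame(b), by = c("rep", "fold"),
             suffixes = c("_a", "_b"))
  d <- m$r_a - m$r_b
  ok <- !is.na(d)
  d <- d[ok]
  if (length(d) < 2) stop("fewer than two paired runs")
  if (stats::sd(d) == 0) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
    df <- length(d) - 1
  } else {
    tt <- stats::t.test(d)
    t_stat <- unname(tt$statistic); p <- tt$p.value; df <- unname(tt$parameter)
  }
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**"
           else if (p < 0.05) "*" else "ns"
  structure(list(model_a = attr(a, "model"), model_b = attr(b, "model"),
                 mean_a = mean(m$r_a[ok]), mean_b = mean(m$r_b[ok]),
                 mean_diff = mean(d), t = t_stat, df = df, p_value = p,
                 stars = stars, n_pairs = length(d)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("%s (mean r = %.3f) vs %s (mean r = %.3f)\n",
              x$model_a, x$mean_a, x$model_b, x$mean_b))
  cat(sprintf("  paired t = %.3f on %s df, p = %.4g %s (n = %d pairs)\n",
              x$t, format(x$df), x$p_value, x$stars, x$n_pairs))
  invisible(x)
}

#' Across-season prediction and correlation scenarios
#'
#' Reproduces the across-season bookkeeping: the model is calibrated on one
#' season's adjusted means (all lines of that season, or the
#' calibration-set lines only) and used to predict either the CS lines'
#' other-season means or the other season's single-season validation set.
#' A correlation block compares raw CS means across seasons (OBV vs OBV)
#' with the correlation of CS GEBVs from per-season full-data fits.
#'
#' @param means_by_season named list of two named numeric vectors of adjusted
#'   means, e.g. `list(S15 = ..., S16 = ...)`.
#' @param K relationship matrix covering all lines.
#' @param line_info data.frame with columns line, set (CS / VS15 / VS16).
#' @param geno complete [geno_matrix()] (for covariate models).
#' @param covariates covariate marker ids for the prediction model
#'   (the across-season scheme uses the QTL-weighted model).
#' @return data.frame (class `season_scenarios`) with columns es, ts, n_es,
#'   n_ts, r; prediction rows first, then the two correlation rows
#'   (`OBV_CS~OBV_CS`, `GEBV_CS~GEBV_CS`).
#' @export
cross_season_predict <- function(means_by_season, K, line_info, geno = NULL,
                                 covariates = character(0)) {
  stopifnot(length(means_by_season) == 2, !is.null(names(means_by_season)))
  seasons <- names(means_by_season)
  set_of <- stats::setNames(line_info$set, line_info$line)
  cs <- line_info$line[line_info$set == "CS"]
  fit_on <- function(ids, season) {
    X <- build_fixed_design(geno %||% NULL_geno(ids), covariates, ids)
    gblup(means_by_season[[season]][ids], K, X = X)
  }
  predict_ids <- function(fit, ids) {
    Xn <- build_fixed_design(geno %||% NULL_geno(ids), covariates, ids,
                             drop_aliased = FALSE)
    predict(fit, K, lines = ids,
            X_new = Xn[, names(fit$beta), drop = FALSE])$gebv
  }
  rows <- list()
  for (i in 1:2) {
    es_season <- seasons[i]; ts_season <- seasons[-i]
    es_all <- names(means_by_season[[es_season]])
    fit <- fit_on(es_all, es_season)
    cs_here <- intersect(cs, intersect(es_all, names(means_by_season[[ts_season]])))
    vs_ts <- setdiff(names(means_by_season[[ts_season]]), es_all)
    for (tgt in list(list(ids = cs_here, label = paste0("CS_", ts_season)),
                     list(ids = vs_ts, label = paste0("VS_", ts_season)))) {
      obs <- means_by_season[[ts_season]][tgt$ids]
      pred <- predict_ids(fit, tgt$ids)
      rows[[length(rows) + 1L]] <- data.frame(
        es = paste0("all_", es_season), ts = tgt$label,
        n_es = length(es_all), n_ts = length(tgt$ids),
        r = stats::cor(obs, pred), stringsAsFactors = FALSE)
    }
  }
  # correlation block on the CS lines
  cs_both <- intersect(intersect(cs, names(means_by_season[[1]])),
                       names(means_by_season[[2]]))
  obv1 <- means_by_season[[1]][cs_both]; obv2 <- means_by_season[[2]][cs_both]
  g1 <- gebv(fit_on(names(means_by_season[[1]]), seasons[1]))[cs_both]
  g2 <- gebv(fit_on(names(means_by_season[[2]]), seasons[2]))[cs_both]
  rows[[length(rows) + 1L]] <- data.frame(
    es = paste0("OBV_CS_", seasons[1]), ts = paste0("OBV_CS_", seasons[2]),
    n_es = length(cs_both), n_ts = length(cs_both),
    r = stats::cor(obv1, obv2), stringsAsFactors = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    es = paste0("GEBV_CS_", seasons[1]), ts = paste0("GEBV_CS_", seasons[2]),
    n_es = length(cs_both), n_ts = length(cs_both),
    r = stats::cor(g1, g2), stringsAsFactors = FALSE)
  structure(do.call(rbind, rows), class = c("season_scenarios", "data.frame"))
}

#' Two-marker haplotype analysis of the major dormancy locus
#'
#' Groups lines by their two-locus homozygous haplotype at the major-locus
#' marker pair (lines with a missing or heterozygous call at either marker
#' are excluded and counted), computes per-class trait means, and tests all
#' pairwise class differences with Welch t-tests under Bonferroni correction.
#'
#' @param geno a [geno_matrix()].
#' @param markers the two marker ids.
#' @param means named numeric vector of line-level trait means.
#' @param alpha familywise significance level (default 0.05).
#' @param min_n classes need at least `min_n` lines to enter the tests.
#' @return list (class `haplotype_analysis`): `classes` (haplotype, n, mean,
#'   sd), `tests` (class_a, class_b, diff, p_raw, p_adj, significant),
#'   `n_excluded`.
#' @export
haplotype_analysis <- function(geno, markers, means, alpha = 0.05,
                               min_n = 3L) {
  stopifnot(inherits(geno, "geno_matrix"), length(markers) == 2)
  absent <- setdiff(markers, colnames(geno$dosage))
  if (length(absent)) stop("marker(s) not in panel: ",
                           paste(absent, collapse = ", "))
  ids <- intersect(rownames(geno$dosage), names(means))
  d <- geno$dosage[ids, markers, drop = FALSE]
  ok <- !is.na(d[, 1]) & !is.na(d[, 2]) & d[, 1] != 1 & d[, 2] != 1
  n_excluded <- sum(!ok)
  d <- d[ok, , drop = FALSE]
  hap <- paste(ifelse(d[, 1] == 0, "maj", "min"),
               ifelse(d[, 2] == 0, "maj", "min"), sep = "/")
  v <- means[rownames(d)]
  classes <- data.frame(
    haplotype = sort(unique(hap)),
    n = as.integer(table(hap)[sort(unique(hap))]),
    mean = tapply(v, hap, mean)[sort(unique(hap))],
    sd = tapply(v, hap, stats::sd)[sort(unique(hap))],
    row.names = NULL, stringsAsFactors = FALSE)
  testable <- classes$haplotype[classes$n >= min_n]
  if (length(testable) < 2)
    stop("fewer than 2 haplotype classes with n >= ", min_n)
  pairs <- utils::combn(testable, 2)
  tests <- data.frame(class_a = pairs[1, ], class_b = pairs[2, ],
                      diff = NA_real_, p_raw = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    va <- v[hap == pairs[1, i]]; vb <- v[hap == pairs[2, i]]
    tt <- stats::t.test(va, vb)  # Welch
    tests$diff[i] <- mean(va) - mean(vb)
    tests$p_raw[i] <- tt$p.value
  }
  tests$p_adj <- stats::p.adjust(tests$p_raw, method = "bonferroni")
  tests$significant <- tests$p_adj < alpha
  structure(list(classes = classes, tests = tests, n_excluded = n_excluded,
                 markers = markers, alpha = alpha),
            class = "haplotype_analysis")
}

#' @export
print.haplotype_analysis <- function(x, ...) {
  cat(sprintf("Haplotype classes at %s / %s (%d lines excluded: missing or heterozygous)\n",
              x$markers[1], x$markers[2], x$n_excluded))
  print(transform(x$classes, mean = round(mean, 3), sd = round(sd, 3)),
        row.names = FALSE)
  cat(sprintf("pairwise Welch tests, Bonferroni-adjusted at alpha = %g:\n",
              x$alpha))
  print(transform(x$tests, diff = round(diff, 3),
                  p_raw = signif(p_raw, 3), p_adj = signif(p_adj, 3)),
        row.names = FALSE)
  invisible(x)
}
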