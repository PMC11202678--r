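test_that("fixed design has intercept plus covariate dosages, dropping aliased columns", {
  fx <- test_panel()
  ids <- rownames(fx$geno$dosage)
  X1 <- build_fixed_design(fx$geno, character(0), ids)
  expect_equal(colnames(X1), "(Intercept)")

  phs <- variant_covariates(fx$arch$panel, "model2_phs")
  expect_length(phs, 3)
  X2 <- build_fixed_design(fx$geno, phs, ids)
  expect_lte(ncol(X2), 4)
  expect_equal(colnames(X2)[1], "(Intercept)")

  q17 <- variant_covariates(fx$arch$panel, "model2_qtl17")
  expect_length(q17, 17)
  rht <- variant_covariates(fx$arch$panel, "model2_rht")
  expect_length(rht, 3)
  expect_length(variant_covariates(fx$arch$panel, "model1"), 0)

  expect_error(build_fixed_design(fx$geno, "no_such_marker", ids), "absent")
  expect_error(build_fixed_design(fx$geno, character(0), character(0)),
               "zero lines")
})

test_that("perfectly collinear covariates are dropped without changing the fit", {
  fx <- test_panel()
  ids <- rownames(fx$geno$dosage)
  y <- simulate_line_means(fx$truth, 0.7, seed = 3)
  mk <- fx$arch$major_markers[1]
  # duplicate the marker column: second copy must be dropped
  g2 <- fx$geno
  g2$dosage <- cbind(g2$dosage, copy_mk = g2$dosage[, mk])
  g2$map <- rbind(g2$map, data.frame(marker = "copy_mk", chrom = "un", pos = 0))
  X <- build_fixed_design(g2, c(mk, "copy_mk"), ids)
  expect_equal(attr(X, "dropped"), "copy_mk")
  f_ref <- gblup(y, fx$A, X = build_fixed_design(fx$geno, mk, ids))
  f_dup <- gblup(y, fx$A, X = X)
  expect_equal(f_dup$logLik, f_ref$logLik, tolerance = 1e-10)
})

test_that("REML hits the noiseless limit and is invariant to phenotype shifts", {
  # noiseless limit needs rank(A) < n - p so zero-residual dimensions exist:
  # use more lines than markers
  fx_low <- test_panel(n = 150, m = 100, seed = 43)
  y <- fx_low$truth  # y = g exactly, no residual noise
  fit <- suppressMessages(gblup(y, fx_low$A))
  expect_gt(fit$lambda, 1e5)  # variance ratio at the upper search bound
  expect_lt(max(abs(fitted(fit) - y)), 1e-4)

  fx <- test_panel()
  y2 <- simulate_line_means(fx$truth, 0.6, seed = 9)
  f0 <- gblup(y2, fx$A)
  fc <- gblup(y2 + 50, fx$A)
  expect_equal(unname(coef(fc)["(Intercept)"] - coef(f0)["(Intercept)"]), 50,
               tolerance = 1e-8)
  expect_equal(fc$u, f0$u, tolerance = 1e-6)
  expect_equal(fc$sigma2_t, f0$sigma2_t, tolerance = 1e-6)
  expect_equal(fc$sigma2_e, f0$sigma2_e, tolerance = 1e-6)

  # breeding values centered when X is the intercept and A has zero row sums
  expect_lt(abs(sum(f0$u)), 1e-6)
})

test_that("profile REML beats a dense grid oracle on simulated data", {
  fx <- test_panel(n = 80, m = 300, seed = 17)
  n <- length(fx$truth)
  X <- matrix(1, n, 1)
  for (s in 1:3) {
    y <- simulate_line_means(fx$truth, c(0.3, 0.6, 0.85)[s], seed = s)
    fit <- gblup(y, fx$A)
    Ar <- unclass(fx$A) + diag(fit$ridge, n)
    grid <- 10^seq(-6, 6, length.out = 50)
    ll <- vapply(grid, function(l) dense_reml_ll(l, as.numeric(y), X, Ar), 0)
    expect_gte(fit$logLik, max(ll) - 1e-6)
    # and the optimum agrees with the dense evaluation at lambda-hat
    expect_equal(fit$logLik,
                 as.numeric(dense_reml_ll(fit$lambda, as.numeric(y), X, Ar)),
                 tolerance = 1e-8)
  }
})

test_that("GBLUP breeding values equal matched-variance ridge-regression predictions", {
  fx <- test_panel(n = 80, m = 300, seed = 17)
  y <- simulate_line_means(fx$truth, 0.6, seed = 11)
  fit <- gblup(y, fx$A)
  p <- attr(fx$A, "p"); d <- attr(fx$A, "denom")
  Z <- sweep(fx$geno$dosage, 2, 2 * p)
  n <- nrow(Z)
  # ridge applied inside the fit corresponds to d*ridge extra diagonal markers
  Zs <- cbind(Z, diag(sqrt(d * fit$ridge), n))
  r <- as.numeric(y - fit$beta[1])
  k <- d * fit$sigma2_e / fit$sigma2_t
  m_hat <- solve(crossprod(Zs) + diag(k, ncol(Zs)), crossprod(Zs, r))
  u_rr <- as.numeric(Zs %*% m_hat)
  expect_lt(max(abs(u_rr - fit$u)), 1e-6)
})

test_that("predictions satisfy the duplicated-line, zero-kinship and whole-panel identities", {
  fx <- test_panel(n = 90, m = 300, seed = 23)
  ids <- names(fx$truth)
  train <- ids[1:70]; target <- ids[71:90]
  y <- simulate_line_means(fx$truth, 0.7, seed = 2)[train]
  fit <- gblup(y, fx$A)

  # (1) a target genotypically identical to a training line gets its BLUP
  A2 <- unclass(fx$A)
  dup <- c(train, "dup_line")
  A_dup <- rbind(cbind(A2[train, train], A2[train, train[1]]),
                 c(A2[train[1], train], A2[train[1], train[1]]))
  dimnames(A_dup) <- list(dup, dup)
  fit_d <- gblup(y, A_dup)
  pr <- predict(fit_d, A_dup, lines = "dup_line")
  expect_equal(pr$genomic, unname(fit_d$u[train[1]]), tolerance = 1e-8)

  # (2) zero kinship to all training lines: prediction is the fixed part
  A_z <- rbind(cbind(A2[train, train], 0), 0)
  dimnames(A_z) <- list(c(train, "alien"), c(train, "alien"))
  A_z["alien", "alien"] <- 1
  fit_z <- gblup(y, A_z)
  pz <- predict(fit_z, A_z, lines = "alien")
  expect_equal(pz$genomic, 0, tolerance = 1e-10)
  expect_equal(pz$gebv, unname(coef(fit_z)["(Intercept)"]), tolerance = 1e-10)

  # (3) two-step conditional prediction equals the whole-panel mixed-model solve
  pred <- predict(fit, fx$A, lines = target)
  Ar <- A2 + diag(fit$ridge, nrow(A2))
  V <- fit$sigma2_t * Ar[train, train] + diag(fit$sigma2_e, length(train))
  r <- as.numeric(y - fit$beta[1])
  u_all <- fit$sigma2_t * (Ar[ids, train] %*% solve(V, r))
  expect_lt(max(abs(pred$genomic - u_all[target, 1])), 1e-6)
})

test_that("variance components are recovered from the model's own generating process", {
  fx <- test_panel(n = 120, m = 400, seed = 29)
  est <- vapply(1:15, function(s) {
    sim <- sim_mvn_y(fx$A, s2t = 0.5, s2e = 0.5, seed = 100 + s)
    fit <- gblup(sim$y, fx$A)
    fit$sigma2_t / (fit$sigma2_t + fit$sigma2_e)
  }, 0)
  expect_equal(mean(est), 0.5, tolerance = 0.08)
})

test_that("predictive ability grows with training size toward sqrt(h2)", {
  fx <- test_panel(n = 200, m = 400, seed = 31)
  ids <- names(fx$truth)
  target <- ids[181:200]
  r_at <- function(n_train) {
    mean(vapply(1:8, function(s) {
      train <- setdiff(ids, target)[1:n_train]
      y <- simulate_line_means(fx$truth, 0.6, seed = 300 + s)[train]
      fit <- gblup(y, fx$A)
      pr <- predict(fit, fx$A, lines = target)
      stats::cor(pr$gebv, fx$truth[target])
    }, 0))
  }
  r_small <- r_at(40); r_big <- r_at(180)
  expect_gt(r_big, r_small)
  expect_lt(r_big, 1)
})
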