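# shared fixtures, built in code and memoized per session

.fixtures <- new.env(parent = emptyenv())

# small complete panel: simulated, recoded, imputed, with kinship and a
# default sprouting architecture + true genetic values
test_panel <- function(n = 150, m = 500, seed = 42, structure = 0.02) {
  key <- paste("panel", n, m, seed, structure, sep = "_")
  if (is.null(.fixtures[[key]])) {
    n3 <- n %/% 3
    spec <- population_spec(
      n_lines = n,
      programs = c(PA = n3, PB = n3, PC = n - 2 * n3),
      season_split = c(CS = n %/% 2, VS15 = (n - n %/% 2) %/% 2,
                       VS16 = n - n %/% 2 - (n - n %/% 2) %/% 2),
      n_markers = m, structure_strength = structure, seed = seed)
    raw <- simulate_population(spec)
    geno <- impute_missing(recode_minor_allele(raw), seed = seed + 1)
    arch <- default_qtl_architecture(geno, "phs", seed = seed + 2)
    truth <- stats::setNames(
      as.vector(geno$dosage[, names(arch$effects)] %*% arch$effects),
      rownames(geno$dosage))
    truth <- truth - mean(truth)
    .fixtures[[key]] <- list(spec = spec, raw = raw, geno = geno,
                             A = vanraden_grm(geno), arch = arch,
                             truth = truth)
  }
  .fixtures[[key]]
}

# random dosage matrix with all markers polymorphic
rand_dosage <- function(n, m, seed) {
  set.seed(seed)
  repeat {
    x <- matrix(sample(0:2, n * m, replace = TRUE, prob = c(0.5, 0.05, 0.45)),
                n, m, dimnames = list(sprintf("l%02d", 1:n),
                                      sprintf("m%03d", 1:m)))
    if (all(apply(x, 2, function(v) length(unique(v)) > 1))) return(x)
  }
}

# dense-matrix restricted log-likelihood oracle for y = Xb + t + e,
# t ~ N(0, s2t * A): evaluated at lambda = s2t/s2e with s2e, beta profiled
dense_reml_ll <- function(lambda, y, X, A) {
  n <- length(y); p <- ncol(X)
  V <- lambda * A + diag(n)
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  s2e <- as.numeric(t(r) %*% Vi %*% r) / (n - p)
  as.numeric(-0.5 * ((n - p) * log(2 * pi * s2e) + determinant(V)$modulus +
                       determinant(XtVX)$modulus + (n - p)))
}

# simulate phenotypes from the GBLUP generating model itself:
# y = mu + t + e, t ~ N(0, s2t * A), e ~ N(0, s2e * I)
sim_mvn_y <- function(A, s2t, s2e, seed, mu = 0) {
  eg <- eigen(unclass(A), symmetric = TRUE)
  d <- pmax(eg$values, 0)
  set.seed(seed)
  t_vec <- as.numeric(eg$vectors %*% (sqrt(d * s2t) * rnorm(length(d))))
  y <- mu + t_vec + rnorm(length(d), 0, sqrt(s2e))
  list(y = stats::setNames(y, rownames(A)),
       t = stats::setNames(t_vec, rownames(A)))
}

# marker-by-marker accumulation oracle for the VanRaden matrix
grm_oracle <- function(dosage) {
  p <- colMeans(dosage) / 2
  d <- 2 * sum(p * (1 - p))
  A <- matrix(0, nrow(dosage), nrow(dosage))
  for (j in seq_len(ncol(dosage))) {
    z <- dosage[, j] - 2 * p[j]
    A <- A + tcrossprod(z)
  }
  A / d
}
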