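test_that("geno_matrix validates its invariants", {
  expect_error(geno_matrix(matrix(c(0, 3), 1, 2)), "0, 1, 2 or NA")
  d <- matrix(0:1, 2, 2, dimnames = list(c("a", "a"), c("x", "y")))
  expect_error(geno_matrix(d), "line ids")
  d <- matrix(0:1, 2, 2, dimnames = list(c("a", "b"), c("x", "x")))
  expect_error(geno_matrix(d), "marker ids")
})

test_that("minor-allele recoding flips majority-coded markers and is idempotent", {
  d <- cbind(m1 = c(2, 2, 0), m2 = c(1, 1, 1), m3 = c(0, 1, 0))
  rownames(d) <- c("a", "b", "c")
  g <- recode_minor_allele(geno_matrix(d))
  expect_equal(unname(g$dosage[, "m1"]), c(0, 0, 2))   # orientation flip
  expect_equal(unname(g$dosage[, "m2"]), c(1, 1, 1))   # MAF 0.5, unchanged
  expect_equal(g$coding, "minor")
  expect_true(all(colMeans(g$dosage) <= 1))
  expect_equal(unname(maf(g)[2]), 0.5)

  for (s in 1:5) {
    r <- geno_matrix(rand_dosage(10, 20, seed = s))
    once <- recode_minor_allele(r)
    expect_identical(recode_minor_allele(once)$dosage, once$dosage)
    expect_true(all(colMeans(once$dosage) <= 1 + 1e-12))
  }
})

test_that("qc_filter applies the strict MAF/missingness rules and collapses duplicates", {
  # 10 markers: 3 below the MAF threshold, 7 at MAF 0.2, no missing
  n <- 100
  low <- replicate(3, c(1, rep(0, n - 1)))   # MAF 0.005
  high <- replicate(7, rep(c(2, 0, 0, 0, 0), n / 5))  # MAF 0.2
  d <- cbind(low, high)
  colnames(d) <- sprintf("m%02d", 1:10)
  rownames(d) <- sprintf("l%03d", 1:n)
  qc <- qc_filter(geno_matrix(d, coding = "minor"))
  expect_equal(qc$report$markers_removed_maf, 3)
  # the 7 high-MAF columns are identical, so 6 collapse as duplicates
  expect_equal(qc$report$duplicates, 6)
  expect_equal(ncol(qc$geno$dosage), 1)

  # monomorphic marker removed
  d2 <- cbind(m1 = rep(0, 10), m2 = rep(c(0, 2), 5))
  rownames(d2) <- letters[1:10]
  qc2 <- qc_filter(geno_matrix(d2, coding = "minor"))
  expect_equal(colnames(qc2$geno$dosage), "m2")

  # removed + retained = input
  expect_equal(qc$report$markers_removed_maf + qc$report$markers_removed_missing +
                 qc$report$duplicates + qc$report$n_markers_out,
               qc$report$n_markers_in)
})

test_that("qc_filter drops bad lines and is order-independent over markers", {
  d <- rand_dosage(30, 40, seed = 7)
  d[1, 1:20] <- NA  # 50% missing line
  g <- recode_minor_allele(geno_matrix(d))
  qc <- qc_filter(g)
  expect_equal(qc$report$lines_removed, "l01")
  expect_false("l01" %in% rownames(qc$geno$dosage))

  perm <- sample(ncol(d))
  qc_perm <- qc_filter(recode_minor_allele(geno_matrix(d[, perm])))
  expect_setequal(colnames(qc_perm$geno$dosage), colnames(qc$geno$dosage))

  # empty result is an error, not silent success
  mono <- geno_matrix(matrix(0, 5, 3, dimnames = list(letters[1:5], c("x", "y", "z"))),
                      coding = "minor")
  expect_error(qc_filter(mono), "no markers left")
})

test_that("binomial imputation is deterministic, moment-correct and degenerate-safe", {
  g <- geno_matrix(rand_dosage(20, 10, seed = 1))
  expect_identical(impute_missing(g), g)  # complete matrix unchanged

  # marker at p = 0.5 with many missing values: mean imputed dosage near 1
  d <- matrix(rep(c(0, 2), 50), 100, 2,
              dimnames = list(sprintf("l%03d", 1:100), c("keep", "fill")))
  big <- do.call(rbind, replicate(100, d, simplify = FALSE))
  rownames(big) <- sprintf("l%05d", 1:10000)
  big[, "fill"] <- NA
  big[1:2, "fill"] <- c(0, 2)  # p-hat = 0.5
  gg <- impute_missing(geno_matrix(big), seed = 3)
  imputed <- gg$dosage[-(1:2), "fill"]
  se <- sqrt(2 * 0.5 * 0.5 / length(imputed))
  expect_lt(abs(mean(imputed) - 1), 3 * se)
  expect_identical(impute_missing(geno_matrix(big), seed = 3)$dosage, gg$dosage)

  # p-hat = 0: imputed value always 0
  d0 <- cbind(a = c(0, 0, NA), b = c(0, 2, 1))
  rownames(d0) <- c("x", "y", "z")
  expect_equal(impute_missing(geno_matrix(d0), seed = 9)$dosage["z", "a"], 0)

  # all-missing marker is an error
  dna <- cbind(a = c(NA, NA), b = c(0, 2))
  rownames(dna) <- c("x", "y")
  expect_error(impute_missing(geno_matrix(dna)), "all calls missing")
})

test_that("vanraden_grm matches the hand example and its structural invariants", {
  A <- vanraden_grm(matrix(c(0, 2, 1, 2, 0, 1), 3, 2,
                           dimnames = list(c("a", "b", "c"), c("m1", "m2"))))
  expect_equal(unclass(A), matrix(c(2, -2, 0, -2, 2, 0, 0, 0, 0), 3, 3,
                                  dimnames = list(c("a", "b", "c"),
                                                  c("a", "b", "c"))),
               ignore_attr = TRUE)
  expect_equal(attr(A, "denom"), 1)

  d <- rand_dosage(25, 60, seed = 11)
  A2 <- vanraden_grm(d)
  expect_lt(max(abs(rowSums(A2))), 1e-8)          # centering => zero row sums
  expect_lt(max(abs(A2 - t(A2))), 1e-10)          # symmetric
  expect_gt(min(eigen(A2, symmetric = TRUE, only.values = TRUE)$values), -1e-8)

  # duplicated line rows give identical kinship entries
  d3 <- rbind(d, dup = d[1, ])
  A3 <- vanraden_grm(d3)
  expect_equal(A3["l01", "l01"], A3["l01", "dup"])
  expect_equal(A3["dup", "dup"], A3["l01", "l01"])

  expect_error(vanraden_grm(matrix(0, 4, 3)), "monomorphic")
})

test_that("PCA variance fractions track the kinship eigenvalues and rank limits", {
  d <- rand_dosage(20, 50, seed = 5)
  pc <- pca_genotypes(d, k = 3)
  expect_true(all(diff(pc$var_fraction) <= 1e-12))
  expect_lte(sum(pc$var_fraction), 1 + 1e-12)
  expect_lt(max(abs(crossprod(pc$scores) -
                      diag(diag(crossprod(pc$scores)), 3))), 1e-8)

  # eigenvalues of the GRM match squared singular values up to the denominator
  A <- vanraden_grm(d)
  ev <- eigen(unclass(A), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ev[1:3], pc$sdev[1:3]^2 * (nrow(d) - 1) / attr(A, "denom"),
               tolerance = 1e-8)

  # rank-1 matrix: single component carries all variance; k beyond rank errors
  r1 <- outer(c(0, 1, 2, 1, 0), c(1, 1, 0, 1, 1, 0))
  dimnames(r1) <- list(paste0("l", 1:5), paste0("m", 1:6))
  pc1 <- pca_genotypes(r1, k = 1)
  expect_equal(pc1$var_fraction, 1, tolerance = 1e-12)
  expect_error(pca_genotypes(r1, k = 3), "rank")
})

test_that("strong program divergence separates programs along PC1", {
  fx <- test_panel(n = 120, m = 300, seed = 21, structure = 0.25)
  pc <- pca_genotypes(fx$geno, k = 2)
  prog <- fx$geno$lines$program
  s <- split(pc$scores[, 1], prog)
  gap <- max(abs(outer(vapply(s, mean, 0), vapply(s, mean, 0), "-")))
  expect_gt(gap, 2 * max(vapply(s, stats::sd, 0)))
})
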