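test_that("population_spec rejects inconsistent specifications", {
  expect_error(population_spec(n_lines = 10, programs = c(A = 4, B = 4),
                               season_split = c(CS = 5, VS15 = 3, VS16 = 2)),
               "sum to n_lines")
  expect_error(population_spec(n_lines = 8, programs = c(A = 4, B = 4),
                               season_split = c(CS = 5, VS15 = 3, VS16 = 2)),
               "n_lines")
  expect_error(population_spec(maf_bounds = c(0.3, 0.1)), "infeasible")
  expect_error(population_spec(maf_bounds = c(0.1, 0.6)), "within")
  expect_error(population_spec(structure_strength = -1), ">= 0")
})

test_that("simulated dosages are closed over {0,1,2} and deterministic under seed", {
  spec <- population_spec(n_lines = 6, programs = c(A = 3, B = 3),
                          season_split = c(CS = 2, VS15 = 2, VS16 = 2),
                          n_markers = 4, structure_strength = 0,
                          maf_bounds = c(0.2, 0.5), seed = 1)
  g <- simulate_population(spec)
  expect_equal(dim(g), c(6L, 4L))
  expect_true(all(g$dosage %in% c(0, 1, 2)))
  g2 <- simulate_population(spec)
  expect_identical(g$dosage, g2$dosage)
  expect_identical(g$lines, g2$lines)
})

test_that("realized MAF respects the bounds and the generated panel passes QC untouched", {
  spec <- population_spec(n_lines = 200, programs = c(A = 100, B = 100),
                          season_split = c(CS = 100, VS15 = 50, VS16 = 50),
                          n_markers = 400, maf_bounds = c(0.05, 0.45),
                          seed = 5)
  g <- simulate_population(spec)
  f <- maf(g)
  expect_true(all(f >= 0.05 & f <= 0.45))
  qc <- qc_filter(recode_minor_allele(g))
  expect_equal(qc$report$n_markers_out, 400)
  expect_equal(length(qc$report$lines_removed), 0)
})

test_that("program and set bookkeeping matches the spec and sets spread across programs", {
  fx <- test_panel()
  tab <- table(fx$raw$lines$program)
  expect_equal(as.integer(tab[names(fx$spec$programs)]),
               unname(as.integer(fx$spec$programs)))
  expect_equal(as.integer(table(fx$raw$lines$set)[c("CS", "VS15", "VS16")]),
               unname(as.integer(fx$spec$season_split[c("CS", "VS15", "VS16")])))
  # every program contributes to every set (the stratified CS selection)
  cross <- table(fx$raw$lines$program, fx$raw$lines$set)
  expect_true(all(cross > 0))
})

test_that("near-zero structure gives near-zero between-program differentiation", {
  # F_ST-style statistic: between-program variance of allele frequencies
  # over p(1-p); the finite-sampling contribution is removed with a
  # program-label permutation null, which is exact under exchangeability
  fst_raw <- function(dosage, prog) {
    pk <- vapply(split(seq_len(nrow(dosage)), prog),
                 function(i) colMeans(dosage[i, , drop = FALSE]) / 2,
                 numeric(ncol(dosage)))
    pbar <- rowMeans(pk)
    keep <- pbar > 0.05 & pbar < 0.95
    mean(apply(pk[keep, , drop = FALSE], 1, stats::var) /
           (pbar[keep] * (1 - pbar[keep])))
  }
  excess <- vapply(1:50, function(s) {
    spec <- population_spec(n_lines = 90, programs = c(A = 30, B = 30, C = 30),
                            season_split = c(CS = 40, VS15 = 25, VS16 = 25),
                            n_markers = 150, structure_strength = 0,
                            maf_bounds = c(0.1, 0.5), seed = s)
    g <- simulate_population(spec)
    obs <- fst_raw(g$dosage, g$lines$program)
    set.seed(1000 + s)
    null <- mean(vapply(1:5, function(i)
      fst_raw(g$dosage, sample(g$lines$program)), 0))
    obs - null
  }, 0)
  expect_lt(abs(mean(excess)), 0.01)

  # and strong divergence is clearly detected by the same statistic
  spec_s <- population_spec(n_lines = 90, programs = c(A = 30, B = 30, C = 30),
                            season_split = c(CS = 40, VS15 = 25, VS16 = 25),
                            n_markers = 150, structure_strength = 0.15,
                            maf_bounds = c(0.1, 0.5), seed = 1)
  gs <- simulate_population(spec_s)
  expect_gt(fst_raw(gs$dosage, gs$lines$program), 0.05)
})

test_that("default QTL architecture places 17 panel + 3 fn markers with exact variance shares", {
  fx <- test_panel()
  arch <- fx$arch
  expect_equal(sum(arch$panel$role == "phs"), 17)
  expect_equal(sum(arch$panel$role == "fn"), 3)
  expect_equal(length(unique(arch$panel$qtl[arch$panel$role == "phs"])), 11)
  expect_false(anyDuplicated(arch$panel$marker) > 0)
  # major pair is adjacent on its chromosome block
  idx <- match(arch$major_markers, fx$geno$map$marker)
  expect_equal(diff(idx), 1L)
  expect_equal(length(unique(fx$geno$map$chrom[idx])), 1L)
  # realized genetic variance equals the target exactly, major share close
  dos <- fx$geno$dosage[, names(arch$effects)]
  g <- as.vector(dos %*% arch$effects)
  expect_equal(stats::var(g), arch$sigma2_g, tolerance = 1e-10)
  g_major <- as.vector(dos[, arch$major_markers] %*%
                         arch$effects[arch$major_markers])
  expect_equal(stats::var(g_major) / stats::var(g), 0.30, tolerance = 0.15)
})

test_that("phenotype simulation honours the design arithmetic and the noise-free limit", {
  fx <- test_panel(n = 60, m = 200, seed = 8)
  des0 <- trial_design_spec(locations = paste0("L", 1:5), n_blocks = 10,
                            season = "S15", mu = 7, sigma2_loc = 0,
                            sigma2_block = 0, sigma2_gxl = 0, sigma2_e = 0)
  sim <- simulate_phenotypes(fx$geno, fx$arch, des0, trait = "FNS", seed = 2)
  # checks appear once per block per location: 10 x 5 = 50 records each
  for (chk in des0$checks)
    expect_equal(sum(sim$pheno$line == chk), 50)
  # entries appear once per location
  expect_equal(unname(table(sim$pheno$line)[rownames(fx$geno$dosage)[1]]), 5L)
  # noise-free: every plot value is mu + g exactly
  g_of <- stats::setNames(sim$truth$g, sim$truth$line)
  expect_equal(sim$pheno$value, 7 + unname(g_of[sim$pheno$line]),
               tolerance = 1e-12)

  expect_error(simulate_phenotypes(fx$geno, fx$arch, des0,
                                   entries = c("nope"), seed = 1),
               "unknown line id")
})

test_that("germination counts hit the endpoints and shift earlier with propensity", {
  expect_equal(simulate_germination_counts(0, 100, 6, seed = 1),
               integer(6))
  all_in <- simulate_germination_counts(1, 100, 6, seed = 1)
  expect_equal(all_in, c(100L, rep(0L, 5)))
  # monotone earliness in expectation: mean GI bracketed by the endpoints
  gi <- vapply(1:200, function(s) {
    cts <- simulate_germination_counts(0.5, 100, 6, seed = s)
    germination_index(cts, 100)
  }, 0)
  expect_gt(mean(gi), 0)
  expect_lt(mean(gi), 1)
  # first-day counts increase with propensity
  d1 <- function(p) mean(vapply(1:100, function(s)
    simulate_germination_counts(p, 50, 6, seed = s)[1], 0L))
  expect_lt(d1(0.2), d1(0.5))
  expect_lt(d1(0.5), d1(0.9))
  cts <- simulate_germination_counts(0.3, 40, 6, seed = 4)
  expect_lte(sum(cts), 40)
})

test_that("simulated line means realize the requested heritability on average", {
  fx <- test_panel()
  h2 <- vapply(1:40, function(s) {
    y <- simulate_line_means(fx$truth, 0.6, seed = s)
    stats::cor(y, fx$truth)^2
  }, 0)
  expect_equal(mean(h2), 0.6, tolerance = 0.05)
})
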