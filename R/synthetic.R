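#' Specification of a synthetic breeding population
#'
#' Describes the cohort the generator emulates: a set of advanced (F6)
#' winter-wheat breeding lines from several programs, split into a
#' calibration set evaluated in two seasons (CS) and two single-season
#' validation sets (VS15, VS16), genotyped at biallelic SNPs.
#'
#' @param n_lines total number of lines.
#' @param programs named integer vector: lines per breeding program;
#'   must sum to `n_lines`.
#' @param season_split named integer vector with elements CS, VS15, VS16;
#'   must sum to `n_lines`.
#' @param n_markers number of SNPs to simulate.
#' @param maf_bounds length-2 bounds (min, max) on minor allele frequency,
#'   within (0, 0.5]. The default (0.01, 0.455) realizes a panel-average
#'   MAF of about 0.233.
#' @param structure_strength Balding-Nichols divergence (an F_ST-like
#'   scalar >= 0) of program allele frequencies around the ancestral pool.
#' @param het_rate residual heterozygosity per marker (F6 lines are nearly
#'   fully inbred; default 1 percent).
#' @param miss_rate fraction of calls set missing at random.
#' @param n_bad_lines number of lines given `bad_line_missing` missingness so
#'   that QC drops them (mimics the 400 -> 397 line bookkeeping).
#' @param bad_line_missing missing fraction for the bad lines.
#' @param seed integer seed.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n_lines = 400L,
                            programs = c(P1 = 80L, P2 = 80L, P3 = 80L,
                                         P4 = 94L, P5 = 20L, P6 = 46L),
                            season_split = c(CS = 200L, VS15 = 100L,
                                             VS16 = 100L),
                            n_markers = 6250L,
                            maf_bounds = c(0.01, 0.455),
                            structure_strength = 0.02,
                            het_rate = 0.01,
                            miss_rate = 0,
                            n_bad_lines = 0L,
                            bad_line_missing = 0.25,
                            seed = 1L) {
  if (sum(programs) != n_lines)
    stop("program sizes must sum to n_lines")
  if (!all(c("CS", "VS15", "VS16") %in% names(season_split)) ||
      sum(season_split) != n_lines)
    stop("season_split must have CS/VS15/VS16 counts summing to n_lines")
  if (length(maf_bounds) != 2 || maf_bounds[1] > maf_bounds[2])
    stop("infeasible maf_bounds: need min <= max")
  if (maf_bounds[1] <= 0 || maf_bounds[2] > 0.5)
    stop("maf_bounds must lie within (0, 0.5]")
  if (structure_strength < 0) stop("structure_strength must be >= 0")
  stopifnot(het_rate >= 0, het_rate <= 1, miss_rate >= 0, miss_rate < 1,
            n_bad_lines >= 0, n_bad_lines <= n_lines)
  structure(list(n_lines = as.integer(n_lines), programs = programs,
                 season_split = season_split,
                 n_markers = as.integer(n_markers),
                 maf_bounds = maf_bounds,
                 structure_strength = structure_strength,
                 het_rate = het_rate, miss_rate = miss_rate,
                 n_bad_lines = as.integer(n_bad_lines),
                 bad_line_missing = bad_line_missing,
                 seed = as.integer(seed)),
            class = "population_spec")
}

# genotype draws at inbreeding F (preserves allele frequencies p):
# n lines x length(p) markers in one block
sample_dosage_block <- function(n, p, f) {
  p2 <- p^2 + f * p * (1 - p)
  p1 <- 2 * p * (1 - p) * (1 - f)
  u <- matrix(stats::runif(n * length(p)), n, length(p))
  P2 <- matrix(p2, n, length(p), byrow = TRUE)
  P12 <- matrix(p2 + p1, n, length(p), byrow = TRUE)
  2 * (u < P2) + 1 * (u >= P2 & u < P12)
}

wheat_chromosomes <- function() {
  paste0(rep(1:7, each = 3), rep(c("A", "B", "D"), times = 7))
}

#' Simulate a structured breeding population
#'
#' Independent-locus genotype simulation: each marker has an ancestral minor
#' allele frequency drawn uniformly inside `maf_bounds`; program-specific
#' frequencies diverge around it by a Balding-Nichols Beta model with
#' parameter `structure_strength`; genotypes are drawn at high inbreeding so
#' residual heterozygosity is `het_rate`. Markers whose realized panel MAF
#' falls outside the bounds are redrawn, so the generated panel passes MAF QC
#' untouched when the bounds allow it.
#'
#' @param spec a [population_spec()].
#' @return a [geno_matrix()] with program and set metadata, chromosome-block
#'   marker map, and `coding = "raw"`.
#' @export
simulate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_lines
  m <- spec$n_markers
  c_fst <- spec$structure_strength
  lo <- spec$maf_bounds[1]; hi <- spec$maf_bounds[2]
  prog_sizes <- spec$programs
  prog_of <- rep(names(prog_sizes), times = prog_sizes)

  with_seed(spec$seed, {
    dosage <- matrix(NA_real_, n, m)
    todo <- seq_len(m)
    for (round in 1:100) {
      p_anc <- stats::runif(length(todo), lo, hi)
      for (k in seq_along(prog_sizes)) {
        rows <- which(prog_of == names(prog_sizes)[k])
        p_k <- if (c_fst > 0) {
          stats::rbeta(length(todo), p_anc * (1 - c_fst) / c_fst,
                       (1 - p_anc) * (1 - c_fst) / c_fst)
        } else p_anc
        f_k <- pmax(0, 1 - spec$het_rate / pmax(2 * p_k * (1 - p_k), 1e-12))
        dosage[rows, todo] <- sample_dosage_block(length(rows), p_k, f_k)
      }
      f_real <- pmin(colMeans(dosage[, todo, drop = FALSE]) / 2,
                     1 - colMeans(dosage[, todo, drop = FALSE]) / 2)
      ok <- f_real >= lo & f_real <= hi
      todo <- todo[!ok]
      if (!length(todo)) break
    }
    if (length(todo))
      warning(length(todo), " markers have realized MAF outside maf_bounds")

    line_ids <- sprintf("L%04d", seq_len(n))
    rownames(dosage) <- line_ids
    colnames(dosage) <- sprintf("M%05d", seq_len(m))
    set_of <- allocate_sets(prog_sizes, spec$season_split)

    # chromosome-block map: contiguous runs of markers per chromosome
    chroms <- wheat_chromosomes()
    chrom_of <- chroms[ceiling(seq_len(m) / ceiling(m / length(chroms)))]
    pos <- stats::ave(seq_len(m), chrom_of, FUN = seq_along) * 1e5

    if (spec$miss_rate > 0) {
      idx <- which(stats::runif(n * m) < spec$miss_rate)
      dosage[idx] <- NA_real_
    }
    bad <- character(0)
    if (spec$n_bad_lines > 0) {
      # one bad line per set where possible, so every set loses a line to QC
      sets_cycle <- rep_len(c("CS", "VS15", "VS16"), spec$n_bad_lines)
      bad <- vapply(seq_len(spec$n_bad_lines), function(i) {
        cand <- setdiff(line_ids[set_of == sets_cycle[i]], bad)
        if (!length(cand)) cand <- setdiff(line_ids, bad)
        cand[sample.int(length(cand), 1L)]
      }, character(1))
      for (b in bad) {
        jj <- sample.int(m, round(spec$bad_line_missing * m))
        dosage[b, jj] <- NA_real_
      }
    }
    geno_matrix(dosage,
                map = data.frame(marker = colnames(dosage), chrom = chrom_of,
                                 pos = pos, stringsAsFactors = FALSE),
                lines = data.frame(line = line_ids, program = prog_of,
                                   set = set_of, stringsAsFactors = FALSE),
                coding = "raw")
  })
}

# spread CS/VS15/VS16 membership across programs by largest remainder,
# respecting both program sizes and set totals
allocate_sets <- function(prog_sizes, season_split) {
  n <- sum(prog_sizes)
  sets <- names(season_split)
  quota <- season_split
  out <- character(n)
  offset <- 0L
  for (k in seq_along(prog_sizes)) {
    np <- prog_sizes[k]
    ideal <- np * season_split / n
    base <- pmin(floor(ideal), quota)
    left <- np - sum(base)
    if (left > 0) {
      ord <- order(ideal - floor(ideal), decreasing = TRUE)
      for (s in rep_len(ord, length(sets) * left)) {
        if (left == 0) break
        if (quota[s] > base[s]) { base[s] <- base[s] + 1L; left <- left - 1L }
      }
    }
    out[offset + seq_len(np)] <- rep(sets, times = base)
    quota <- quota - base
    offset <- offset + np
  }
  out
}

#' QTL architecture for a simulated trait
#'
#' Defines the causal model of one trait: a major dormancy locus carried by
#' two adjacent markers (three observable homozygous haplotype classes, the
#' *Phs-A1* pattern), additional tracked QTL-panel markers with moderate
#' effects, and a polygenic background of many small effects. A separate
#' three-marker set (T1RS.1BL / Rht-B1 / Rht-D1 analogues) tags loci that
#' affect falling number per se rather than sprouting.
#'
#' @param effects named numeric vector of additive effects (trait units per
#'   minor-allele copy) keyed by marker id.
#' @param panel data.frame with columns `marker`, `qtl` (QTL group label) and
#'   `role` (`"phs"` for the 17-marker sprouting panel, `"fn"` for the three
#'   falling-number loci).
#' @param major_markers the two adjacent marker ids forming the major-locus
#'   haplotype.
#' @param sigma2_g target genetic variance of the trait.
#' @return an object of class `qtl_architecture`.
#' @export
qtl_architecture <- function(effects, panel, major_markers,
                             sigma2_g = 1) {
  stopifnot(is.numeric(effects), !is.null(names(effects)))
  stopifnot(all(c("marker", "qtl", "role") %in% names(panel)))
  if (anyDuplicated(panel$marker))
    stop("each panel marker must map to exactly one QTL group")
  if (length(major_markers) != 2)
    stop("major_markers must name exactly two markers")
  structure(list(effects = effects, panel = panel,
                 major_markers = major_markers, sigma2_g = sigma2_g),
            class = "qtl_architecture")
}

#' Build a default QTL architecture on a simulated panel
#'
#' Places the 17-marker sprouting QTL panel (11 QTL groups, including a
#' three-marker major locus on the 4A block whose first two markers form the
#' haplotype pair) and the three falling-number loci on the panel's marker
#' grid, then scales effects so that on the realized genotypes the major
#' locus explains `major_share` of the genetic variance (for a `"phs"` trait)
#' or the falling-number loci explain `fn_share` (for an `"fn"` trait), with
#' a polygenic background making up the rest. Total genetic variance is
#' scaled to `sigma2_g` exactly on the realized genotypes.
#'
#' @param geno a [geno_matrix()] from [simulate_population()].
#' @param trait_class `"phs"` (sprouting trait: major locus + panel +
#'   polygenic), `"fn"` (falling number per se: fn loci + polygenic) or
#'   `"neutral"` (purely polygenic).
#' @param major_share genetic-variance share of the major two-marker locus.
#' @param panel_share share carried by the remaining panel markers.
#' @param fn_share share carried by the three fn loci for an `"fn"` trait.
#' @param n_polygenic number of background causal markers.
#' @param sigma2_g target genetic variance.
#' @param seed integer seed for choosing background markers and effect signs.
#' @return a [qtl_architecture()].
#' @export
default_qtl_architecture <- function(geno, trait_class = c("phs", "fn", "neutral"),
                                     major_share = 0.30, panel_share = 0.15,
                                     fn_share = 0.25, n_polygenic = 300L,
                                     sigma2_g = 1, seed = 1L) {
  trait_class <- match.arg(trait_class)
  stopifnot(inherits(geno, "geno_matrix"))
  panel <- place_qtl_panel(geno)
  dos <- geno$dosage
  dos[is.na(dos)] <- 0  # effects defined on called genotypes; NA rare

  with_seed(seed + 7L, {
    major <- panel$marker[panel$qtl == "PhsA1_4A"][1:2]
    phs_minor <- setdiff(panel$marker[panel$role == "phs"], major)
    fn_mk <- panel$marker[panel$role == "fn"]
    free <- setdiff(colnames(dos), panel$marker)
    poly <- sample(free, min(n_polygenic, length(free)))

    raw <- c(stats::setNames(c(-1, -0.6), major),
             stats::setNames(stats::rnorm(length(phs_minor), 0, 1), phs_minor),
             stats::setNames(stats::rnorm(length(fn_mk), 0, 1), fn_mk),
             stats::setNames(stats::rnorm(length(poly), 0, 1), poly))

    shares <- switch(trait_class,
      phs = c(major = major_share, panel = panel_share, fn = 0,
              poly = 1 - major_share - panel_share),
      fn = c(major = 0, panel = 0, fn = fn_share, poly = 1 - fn_share),
      neutral = c(major = 0, panel = 0, fn = 0, poly = 1))
    stopifnot(all(shares >= 0))

    blocks <- list(major = major, panel = phs_minor, fn = fn_mk, poly = poly)
    effects <- numeric(0)
    for (b in names(blocks)) {
      mk <- blocks[[b]]
      if (shares[b] == 0 || !length(mk)) next
      gb <- as.vector(dos[, mk, drop = FALSE] %*% raw[mk])
      v <- stats::var(gb)
      if (v <= 0) stop("degenerate genetic-variance block: ", b)
      effects <- c(effects, raw[mk] * sqrt(shares[b] * sigma2_g / v))
    }
    # rescale the total so var(g) = sigma2_g exactly on this panel
    g <- as.vector(dos[, names(effects), drop = FALSE] %*% effects)
    effects <- effects * sqrt(sigma2_g / stats::var(g))
    qtl_architecture(effects, panel, major, sigma2_g = sigma2_g)
  })
}

# choose panel marker indices on their nominal chromosome blocks:
# 17 sprouting-panel markers in 11 QTL groups + 3 falling-number loci
place_qtl_panel <- function(geno) {
  groups <- list(
    PHS_1A = c("1A", 1), PHS_1D_1 = c("1D", 1), PHS_1D_2 = c("1D", 1),
    PHS_2B = c("2B", 2), TaMFT_3A = c("3A", 1), PhsA1_4A = c("4A", 3),
    PHS_5A = c("5A", 1), PHS_5B = c("5B", 2), PinbD1_5D = c("5D", 3),
    PHS_5D = c("5D", 1), PHS_7A = c("7A", 1))
  fn_groups <- list(T1RS.1BL = "1B", RhtB1 = "4B", RhtD1 = "4D")
  chrom <- geno$map$chrom
  have_chrom <- !all(is.na(chrom))
  used <- integer(0)
  pick <- function(chr, k, adjacent = FALSE) {
    cand <- if (have_chrom && any(chrom == chr, na.rm = TRUE))
      setdiff(which(chrom == chr), used) else
      setdiff(seq_along(geno$map$marker), used)
    if (length(cand) < k)  # chromosome block too small: fall back to any free markers
      cand <- setdiff(seq_along(geno$map$marker), used)
    if (length(cand) < k) stop("not enough markers to place the QTL panel")
    if (adjacent) {
      # first run of k consecutive indices
      runs <- which(diff(cand, lag = k - 1) == k - 1)
      start <- if (length(runs)) runs[1] else 1L
      cand[start + 0:(k - 1)]
    } else {
      cand[unique(floor(seq(1, length(cand), length.out = k)))]
    }
  }
  rows <- list()
  for (q in names(groups)) {
    k <- as.integer(groups[[q]][2])
    idx <- pick(groups[[q]][1], k, adjacent = (q == "PhsA1_4A"))
    used <- c(used, idx)
    rows[[q]] <- data.frame(marker = geno$map$marker[idx], qtl = q,
                            role = "phs", stringsAsFactors = FALSE)
  }
  for (q in names(fn_groups)) {
    idx <- pick(fn_groups[[q]], 1)
    used <- c(used, idx)
    rows[[q]] <- data.frame(marker = geno$map$marker[idx], qtl = q,
                            role = "fn", stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Multi-environment augmented trial design
#'
#' One season's field-trial layout: several locations, each laid out as an
#' unreplicated augmented design with `n_blocks` blocks, every check variety
#' once per block, and the unreplicated entries spread across blocks.
#'
#' @param locations character vector of location names.
#' @param n_blocks blocks per location (default 10).
#' @param checks ids of the repeated check varieties (default 3).
#' @param season season label attached to the records.
#' @param mu trait grand mean.
#' @param sigma2_loc,sigma2_block,sigma2_gxl,sigma2_e variance components of
#'   the generating model (location, block within location, genotype x
#'   location, plot residual). `sigma2_e = NULL` back-solves the residual
#'   variance from `target_h2`.
#' @param target_h2 entry-mean heritability used to back-solve `sigma2_e`
#'   when it is not given: with L locations and genetic variance s2g,
#'   `sigma2_e = L * s2g * (1/h2 - 1) - sigma2_gxl` (must be >= 0).
#' @return an object of class `trial_design_spec`.
#' @export
trial_design_spec <- function(locations = paste0("Loc", 1:5),
                              n_blocks = 10L,
                              checks = c("CHK1", "CHK2", "CHK3"),
                              season = "S15", mu = 0,
                              sigma2_loc = 0.5, sigma2_block = 0.2,
                              sigma2_gxl = 0.2, sigma2_e = NULL,
                              target_h2 = 0.85) {
  stopifnot(length(locations) >= 1, n_blocks >= 1)
  vv <- c(sigma2_loc, sigma2_block, sigma2_gxl, sigma2_e)
  if (any(vv < 0)) stop("all variance components must be >= 0")
  if (is.null(sigma2_e))
    stopifnot(target_h2 > 0, target_h2 <= 1)
  structure(list(locations = locations, n_blocks = as.integer(n_blocks),
                 checks = checks, season = season, mu = mu,
                 sigma2_loc = sigma2_loc, sigma2_block = sigma2_block,
                 sigma2_gxl = sigma2_gxl, sigma2_e = sigma2_e,
                 target_h2 = target_h2),
            class = "trial_design_spec")
}

#' Simulate plot-level phenotypes for one trait
#'
#' Generates records under the model the trial analysis assumes:
#' \deqn{y = \mu + loc + block(loc) + g + g \times loc + e}
#' with the genetic value \eqn{g} computed from the architecture's additive
#' effects, and independent normal draws for the other terms. Checks not in
#' the genotype panel get genetic values drawn from the entry distribution.
#'
#' @param geno a [geno_matrix()]; its lines (optionally restricted by
#'   `entries`) are the unreplicated entries.
#' @param arch a [qtl_architecture()].
#' @param design a [trial_design_spec()].
#' @param entries optional subset of line ids to use as entries.
#' @param trait trait name attached to the records.
#' @param seed integer seed.
#' @return list with `pheno` (plot records: line, season, location, block,
#'   trait, value), `truth` (line, g, is_check) and `var_components`
#'   (the generating values actually used, including the back-solved
#'   `sigma2_e`).
#' @export
simulate_phenotypes <- function(geno, arch, design, entries = NULL,
                                trait = "FNS", seed = 1L) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(arch, "qtl_architecture"),
            inherits(design, "trial_design_spec"))
  if (is.null(entries)) entries <- rownames(geno$dosage)
  missing_ids <- setdiff(entries, rownames(geno$dosage))
  if (length(missing_ids))
    stop("unknown line id(s) in design: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  dos <- geno$dosage[entries, names(arch$effects), drop = FALSE]
  dos[is.na(dos)] <- 0
  g_entry <- stats::setNames(as.vector(dos %*% arch$effects), entries)
  g_entry <- g_entry - mean(g_entry)
  s2g <- stats::var(g_entry)
  L <- length(design$locations)
  s2e <- design$sigma2_e
  if (is.null(s2e)) {
    s2e <- L * s2g * (1 / design$target_h2 - 1) - design$sigma2_gxl
    if (s2e < -1e-9)
      stop("target_h2 infeasible given sigma2_gxl; residual variance would be negative")
    s2e <- max(s2e, 0)
  }

  with_seed(seed, {
    g_check <- stats::setNames(
      stats::rnorm(length(design$checks), 0, sqrt(s2g)), design$checks)
    g_all <- c(g_entry, g_check[setdiff(design$checks, names(g_entry))])
    ids <- c(names(g_entry), setdiff(design$checks, names(g_entry)))
    gxl <- matrix(stats::rnorm(length(ids) * L, 0, sqrt(design$sigma2_gxl)),
                  length(ids), L, dimnames = list(ids, design$locations))
    loc_eff <- stats::setNames(
      stats::rnorm(L, 0, sqrt(design$sigma2_loc)), design$locations)

    recs <- vector("list", L)
    for (l in seq_len(L)) {
      loc <- design$locations[l]
      blk_eff <- stats::rnorm(design$n_blocks, 0, sqrt(design$sigma2_block))
      # entries randomly assigned across blocks, once per location
      perm <- sample(entries)
      blk_of <- rep_len(seq_len(design$n_blocks), length(perm))
      plot_line <- c(perm, rep(design$checks, each = design$n_blocks))
      plot_blk <- c(blk_of, rep(seq_len(design$n_blocks),
                                times = length(design$checks)))
      e <- stats::rnorm(length(plot_line), 0, sqrt(s2e))
      val <- design$mu + loc_eff[loc] + blk_eff[plot_blk] +
        g_all[plot_line] + gxl[cbind(plot_line, loc)] + e
      recs[[l]] <- data.frame(line = plot_line, season = design$season,
                              location = loc, block = plot_blk,
                              trait = trait, value = as.numeric(val),
                              stringsAsFactors = FALSE)
    }
    pheno <- do.call(rbind, recs)
    rownames(pheno) <- NULL
    list(pheno = pheno,
         truth = data.frame(line = ids, g = as.numeric(g_all[ids]),
                            is_check = ids %in% design$checks,
                            stringsAsFactors = FALSE),
         var_components = c(sigma2_g = s2g, sigma2_loc = design$sigma2_loc,
                            sigma2_block = design$sigma2_block,
                            sigma2_gxl = design$sigma2_gxl, sigma2_e = s2e))
  })
}

#' Simulate entry-mean phenotypes at a target heritability
#'
#' Convenience generator for line-level adjusted-mean analogues: returns
#' `g + e` with `var(e)` chosen so the squared accuracy of the means equals
#' `h2` in expectation. Used for prediction experiments that operate on
#' adjusted means directly.
#'
#' @param g named numeric vector of true genetic values.
#' @param h2 entry-mean heritability in (0, 1].
#' @param seed integer seed.
#' @return named numeric vector of simulated means.
#' @export
simulate_line_means <- function(g, h2, seed = 1L) {
  stopifnot(is.numeric(g), !is.null(names(g)), h2 > 0, h2 <= 1)
  s2e <- stats::var(g) * (1 / h2 - 1)
  with_seed(seed, g + stats::rnorm(length(g), 0, sqrt(s2e)))
}

#' Simulate daily germination counts for one seed lot
#'
#' Each seed germinates on day d with geometric waiting time: probability
#' `propensity * (1 - propensity)^(d-1)`; seeds not germinating within
#' `n_days` stay dormant. Higher propensity shifts germination earlier, so
#' the germination index is stochastically increasing in propensity.
#'
#' @param propensity daily germination probability in \[0, 1\].
#' @param n_seeds seeds plated (default 100).
#' @param n_days days counted (default 6).
#' @param seed integer seed.
#' @return integer vector of daily counts (length `n_days`, sum <= `n_seeds`).
#' @export
simulate_germination_counts <- function(propensity, n_seeds = 100L,
                                        n_days = 6L, seed = 1L) {
  stopifnot(propensity >= 0, propensity <= 1, n_days >= 1, n_seeds >= 0)
  if (propensity == 0) return(integer(n_days))
  with_seed(seed, {
    day <- stats::rgeom(n_seeds, propensity) + 1L
    tabulate(day[day <= n_days], nbins = n_days)
  })
}

#' Write the true simulated effects and breeding values
#'
#' @param arch a [qtl_architecture()].
#' @param truth the `truth` data.frame from [simulate_phenotypes()].
#' @param effects_file,bv_file output CSV paths.
#' @export
write_truth_csv <- function(arch, truth, effects_file, bv_file) {
  utils::write.csv(data.frame(marker = names(arch$effects),
                              effect = as.numeric(arch$effects)),
                   effects_file, row.names = FALSE, quote = FALSE)
  utils::write.csv(truth, bv_file, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
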