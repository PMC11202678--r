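#' Default pipeline configuration
#'
#' The configuration that reproduces the study conditions on synthetic data:
#' 400 lines from six breeding programs (80/80/80/94/20/46) split
#' 200 CS + 100 VS15 + 100 VS16, 6,500 simulated SNPs (MAF uniform on
#' (0.01, 0.455)), three lines with heavy missingness so QC drops them,
#' two seasons of five-location augmented trials with ten blocks and three
#' repeated checks, five sprouting-related traits at their reported
#' heritability levels, and 10 x 5-fold program-stratified CV for the four
#' model variants.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @return a nested list understood by [run_pipeline()].
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    population = list(n_lines = 400L, n_markers = 6250L,
                      n_bad_lines = 3L, structure_strength = 0.02),
    locations = list(S15 = paste0("Loc", 1:5, "_S15"),
                     S16 = paste0("Loc", 1:5, "_S16")),
    n_blocks = 10L,
    checks = c("CHK1", "CHK2", "CHK3"),
    traits = list(
      LS  = list(class = "phs", target_h2 = 0.66, mu = 5, sigma2_g = 2.25,
                 major_share = 0.20, scale = "ordinal9"),
      GI  = list(class = "phs", target_h2 = 0.75, mu = 0.5, sigma2_g = 0.015,
                 major_share = 0.25, scale = "unit"),
      FN1 = list(class = "fn", target_h2 = 0.62, mu = 300, sigma2_g = 2500,
                 major_share = 0, scale = "continuous"),
      FN2 = list(class = "phs", target_h2 = 0.77, mu = 250, sigma2_g = 2500,
                 major_share = 0.30, scale = "continuous"),
      FNS = list(class = "phs", target_h2 = 0.86, mu = 280, sigma2_g = 2500,
                 major_share = 0.30, scale = "continuous")),
    qc = list(maf_min = 0.01, max_missing = 0.05, line_max_missing = 0.20),
    cv = list(k = 5L, reps = 10L),
    models = c("model1", "model2_qtl17", "model2_phs", "model2_rht"),
    season_model = "model2_qtl17",
    haplotype_trait = "FNS")
}

#' Read a pipeline configuration from YAML
#'
#' @param file YAML file with the structure of [default_config()]; missing
#'   entries fall back to the defaults.
#' @return a validated configuration list.
#' @export
read_config <- function(file) {
  user <- yaml::read_yaml(file)
  cfg <- utils::modifyList(default_config(), user)
  # a user trait list replaces the default set rather than merging into it
  if (!is.null(user$traits)) cfg$traits <- user$traits
  # YAML maps parse as lists; the spec constructors expect named vectors
  for (f in c("programs", "season_split"))
    if (!is.null(cfg$population[[f]]))
      cfg$population[[f]] <- unlist(cfg$population[[f]])
  cfg$locations <- lapply(cfg$locations, unlist)
  cfg$models <- unlist(cfg$models)
  cfg$checks <- unlist(cfg$checks)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed))
  known_models <- c("model1", "model2_qtl17", "model2_phs", "model2_rht")
  bad <- setdiff(cfg$models, known_models)
  if (length(bad)) stop("unknown model variant(s): ", paste(bad, collapse = ", "))
  for (tr in names(cfg$traits)) {
    t <- cfg$traits[[tr]]
    if (!t$class %in% c("phs", "fn", "neutral"))
      stop("unknown trait class for ", tr, ": ", t$class)
    if (t$target_h2 <= 0 || t$target_h2 > 1)
      stop("target_h2 out of (0,1] for trait ", tr)
  }
  if (!cfg$haplotype_trait %in% names(cfg$traits))
    stop("haplotype_trait not in trait list: ", cfg$haplotype_trait)
  if (!all(c("S15", "S16") %in% names(cfg$locations)))
    stop("locations must name seasons S15 and S16")
  invisible(cfg)
}

apply_trait_scale <- function(x, scale) {
  switch(scale,
         continuous = x,
         unit = pmin(pmax(x, 0), 1),
         ordinal9 = pmin(pmax(round(x), 1), 9),
         stop("unknown trait scale: ", scale))
}

season_sets <- list(S15 = c("CS", "VS15"), S16 = c("CS", "VS16"))

#' Run the full synthetic study pipeline
#'
#' Sequences the stages simulate -> qc -> trial-stats -> predict-cv ->
#' predict-season -> haplotypes, each writing its outputs as CSV/TSV files
#' in `out_dir` and reading its inputs back from the previous stage's files
#' (every stage can be rerun from disk). A manifest with the md5 of every
#' output, the seeds and the package version is written last; rerunning the
#' same configuration is bit-identical.
#'
#' @param config a configuration list ([default_config()]) or path to a
#'   YAML file.
#' @param out_dir output directory (created if needed).
#' @param stages which stages to run, in pipeline order.
#' @return invisibly, the manifest data.frame.
#' @export
run_pipeline <- function(config = default_config(), out_dir = "phsgp_run",
                         stages = c("simulate", "qc", "trial-stats",
                                    "predict-cv", "predict-season",
                                    "haplotypes")) {
  cfg <- if (is.character(config)) read_config(config) else config
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(out_dir, ...)
  all_stages <- c("simulate", "qc", "trial-stats", "predict-cv",
                  "predict-season", "haplotypes")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)

  if ("simulate" %in% stages) stage_simulate(cfg, path)
  if ("qc" %in% stages) stage_qc(cfg, path)
  if ("trial-stats" %in% stages) stage_trial_stats(cfg, path)
  if ("predict-cv" %in% stages) stage_predict_cv(cfg, path)
  if ("predict-season" %in% stages) stage_predict_season(cfg, path)
  if ("haplotypes" %in% stages) stage_haplotypes(cfg, path)

  files <- sort(setdiff(list.files(out_dir), "manifest.csv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE)
  meta <- data.frame(file = c("(seed)", "(package)"),
                     md5 = c(as.character(cfg$seed),
                             as.character(utils::packageVersion("phsgp"))),
                     stringsAsFactors = FALSE)
  utils::write.csv(rbind(meta, manifest), path("manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

stage_fail <- function(stage, e) {
  stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
       call. = FALSE)
}

stage_simulate <- function(cfg, path) {
  tryCatch({
    pop <- do.call(population_spec, c(cfg$population, list(seed = cfg$seed)))
    geno <- simulate_population(pop)
    write_dosage_table(geno, path("genotypes.tsv"))
    write_genotypes_vcf(geno, path("genotypes.vcf"))
    phenos <- list(); truths <- list(); panel <- NULL
    for (i in seq_along(cfg$traits)) {
      tr <- names(cfg$traits)[i]
      t <- cfg$traits[[tr]]
      arch <- default_qtl_architecture(
        geno, trait_class = t$class,
        major_share = if (t$class == "phs") t$major_share else 0.30,
        sigma2_g = t$sigma2_g, seed = cfg$seed + 100L * i)
      if (is.null(panel)) {
        panel <- arch$panel
        utils::write.csv(panel, path("qtl_panel.csv"), row.names = FALSE,
                         quote = FALSE)
      }
      utils::write.csv(
        data.frame(marker = names(arch$effects), trait = tr,
                   effect = as.numeric(arch$effects)),
        path(sprintf("true_effects_%s.csv", tr)), row.names = FALSE,
        quote = FALSE)
      for (s in c("S15", "S16")) {
        entries <- geno$lines$line[geno$lines$set %in% season_sets[[s]]]
        design <- trial_design_spec(
          locations = cfg$locations[[s]], n_blocks = cfg$n_blocks,
          checks = cfg$checks, season = s, mu = t$mu,
          sigma2_loc = 0.5 * t$sigma2_g, sigma2_block = 0.2 * t$sigma2_g,
          sigma2_gxl = 0.2 * t$sigma2_g, target_h2 = t$target_h2)
        sim <- simulate_phenotypes(geno, arch, design, entries = entries,
                                   trait = tr,
                                   seed = cfg$seed + 100L * i +
                                     ifelse(s == "S15", 1L, 2L))
        sim$pheno$value <- apply_trait_scale(sim$pheno$value, t$scale)
        phenos[[length(phenos) + 1L]] <- sim$pheno
        truths[[length(truths) + 1L]] <- cbind(sim$truth, trait = tr,
                                               season = s)
      }
    }
    write_phenotypes_csv(do.call(rbind, phenos), path("phenotypes.csv"))
    utils::write.csv(do.call(rbind, truths), path("true_breeding_values.csv"),
                     row.names = FALSE, quote = FALSE)
  }, error = function(e) stage_fail("simulate", e))
}

read_stage_geno <- function(path, which = "genotypes_qc.tsv") {
  f <- path(which)
  if (!file.exists(f))
    stop("required input ", basename(f), " not found; run the earlier stage first")
  read_dosage_table(f, map_file = paste0(f, ".map.tsv"),
                    lines_file = paste0(f, ".lines.tsv"),
                    coding = if (which == "genotypes.tsv") "raw" else "minor")
}

stage_qc <- function(cfg, path) {
  tryCatch({
    geno <- read_stage_geno(path, "genotypes.tsv")
    qc <- qc_filter(recode_minor_allele(geno),
                    maf_min = cfg$qc$maf_min,
                    max_missing = cfg$qc$max_missing,
                    line_max_missing = cfg$qc$line_max_missing)
    imputed <- impute_missing(qc$geno, seed = cfg$seed + 11L)
    write_dosage_table(imputed, path("genotypes_qc.tsv"))
    write_qc_report(qc$report, path("qc_report.csv"))
    A <- vanraden_grm(imputed)
    write_grm_csv(A, path("grm.csv"))
    pc <- pca_genotypes(imputed, k = 2)
    utils::write.csv(
      data.frame(line = rownames(pc$scores), pc$scores,
                 check.names = FALSE),
      path("pca_scores.csv"), row.names = FALSE, quote = FALSE)
    utils::write.csv(
      data.frame(component = paste0("PC", seq_along(pc$var_fraction)),
                 var_fraction = round(pc$var_fraction, 6)),
      path("pca_variance.csv"), row.names = FALSE, quote = FALSE)
  }, error = function(e) stage_fail("qc", e))
}

stage_trial_stats <- function(cfg, path) {
  tryCatch({
    pheno <- read_phenotypes_csv(path("phenotypes.csv"))
    stats_tab <- trial_summary(pheno)
    utils::write.csv(stats_tab, path("trial_stats.csv"), row.names = FALSE,
                     quote = FALSE)
    out <- list()
    for (tr in unique(pheno$trait)) for (s in unique(pheno$season)) {
      m <- tryCatch(adjusted_means(pheno, tr, s), error = function(e) NULL)
      if (!is.null(m))
        out[[length(out) + 1L]] <- data.frame(line = names(m), trait = tr,
                                              season = s, mean = as.numeric(m),
                                              stringsAsFactors = FALSE)
    }
    utils::write.csv(do.call(rbind, out), path("adjusted_means.csv"),
                     row.names = FALSE, quote = FALSE)
  }, error = function(e) stage_fail("trial-stats", e))
}

read_means <- function(path) {
  f <- path("adjusted_means.csv")
  if (!file.exists(f)) stop("adjusted_means.csv not found; run trial-stats first")
  utils::read.csv(f, stringsAsFactors = FALSE)
}

read_grm <- function(path) {
  tab <- utils::read.csv(path("grm.csv"), check.names = FALSE)
  A <- as.matrix(tab[, -1])
  rownames(A) <- tab[[1]]
  A
}

means_vector <- function(means, tr, s, lines) {
  m <- means[means$trait == tr & means$season == s, , drop = FALSE]
  v <- stats::setNames(m$mean, m$line)
  v[intersect(lines, names(v))]
}

stage_predict_cv <- function(cfg, path) {
  tryCatch({
    geno <- read_stage_geno(path)
    means <- read_means(path)
    A <- read_grm(path)
    panel <- utils::read.csv(path("qtl_panel.csv"), stringsAsFactors = FALSE)
    cv_rows <- list(); cmp_rows <- list()
    for (s in c("S15", "S16")) {
      lines <- geno$lines[geno$lines$set %in% season_sets[[s]], , drop = FALSE]
      plan <- make_folds(lines, k = cfg$cv$k, reps = cfg$cv$reps,
                         seed = cfg$seed + ifelse(s == "S15", 21L, 22L))
      for (tr in names(cfg$traits)) {
        y <- means_vector(means, tr, s, lines$line)
        if (length(y) < 10) next
        res <- list()
        for (mod in cfg$models) {
          covs <- variant_covariates(panel, mod)
          res[[mod]] <- cross_validate(y, A, plan, geno = geno,
                                       covariates = covs, model = mod)
          cv_rows[[length(cv_rows) + 1L]] <- cbind(
            season = s, trait = tr, model = mod, as.data.frame(res[[mod]]))
        }
        if ("model1" %in% names(res)) {
          for (mod in setdiff(names(res), "model1")) {
            cmp <- compare_models(res[[mod]], res[["model1"]])
            cmp_rows[[length(cmp_rows) + 1L]] <- data.frame(
              season = s, trait = tr, model = mod,
              mean_model = cmp$mean_a, mean_model1 = cmp$mean_b,
              mean_diff = cmp$mean_diff, t = cmp$t, p_value = cmp$p_value,
              stars = cmp$stars, stringsAsFactors = FALSE)
          }
        }
      }
    }
    utils::write.csv(do.call(rbind, cv_rows), path("cv_results.csv"),
                     row.names = FALSE, quote = FALSE)
    if (length(cmp_rows))
      utils::write.csv(do.call(rbind, cmp_rows), path("cv_comparisons.csv"),
                       row.names = FALSE, quote = FALSE)
  }, error = function(e) stage_fail("predict-cv", e))
}

stage_predict_season <- function(cfg, path) {
  tryCatch({
    geno <- read_stage_geno(path)
    means <- read_means(path)
    A <- read_grm(path)
    panel <- utils::read.csv(path("qtl_panel.csv"), stringsAsFactors = FALSE)
    covs <- variant_covariates(panel, cfg$season_model)
    rows <- list()
    for (tr in names(cfg$traits)) {
      mbs <- list(
        S15 = means_vector(means, tr, "S15", geno$lines$line),
        S16 = means_vector(means, tr, "S16", geno$lines$line))
      if (any(vapply(mbs, length, 0L) < 10)) next
      sc <- cross_season_predict(mbs, A, geno$lines, geno = geno,
                                 covariates = covs)
      rows[[length(rows) + 1L]] <- cbind(trait = tr, as.data.frame(sc))
    }
    utils::write.csv(do.call(rbind, rows), path("season_scenarios.csv"),
                     row.names = FALSE, quote = FALSE)
  }, error = function(e) stage_fail("predict-season", e))
}

stage_haplotypes <- function(cfg, path) {
  tryCatch({
    geno <- read_stage_geno(path)
    means <- read_means(path)
    panel <- utils::read.csv(path("qtl_panel.csv"), stringsAsFactors = FALSE)
    major <- panel$marker[panel$qtl == "PhsA1_4A"][1:2]
    if (!all(major %in% colnames(geno$dosage)))
      stop("major-locus markers were removed by QC")
    tr <- cfg$haplotype_trait
    cls <- list(); tst <- list()
    for (s in c("S15", "S16")) {
      v <- means_vector(means, tr, s, geno$lines$line)
      ha <- haplotype_analysis(geno, major, v)
      cls[[s]] <- cbind(season = s, trait = tr, ha$classes)
      tst[[s]] <- cbind(season = s, trait = tr, ha$tests)
    }
    utils::write.csv(do.call(rbind, cls), path("haplotype_classes.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(do.call(rbind, tst), path("haplotype_tests.csv"),
                     row.names = FALSE, quote = FALSE)
  }, error = function(e) stage_fail("haplotypes", e))
}
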