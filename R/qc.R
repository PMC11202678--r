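#' Genotype quality control
#'
#' Applies the marker- and line-level filters used for the breeding panel:
#' lines with too many missing calls or excess heterozygosity (heterogeneity
#' in nominally inbred F6 material) are dropped first, then markers are
#' filtered on minor allele frequency (strictly greater than `maf_min`) and
#' missing fraction (strictly less than `max_missing`), and exactly duplicated
#' marker columns are collapsed to one representative.
#'
#' @param g a recoded [geno_matrix()].
#' @param maf_min markers retained only if MAF > `maf_min`.
#' @param max_missing markers retained only if missing fraction < `max_missing`.
#' @param line_max_missing lines dropped if missing fraction > `line_max_missing`.
#' @param line_max_het lines dropped if heterozygote fraction > `line_max_het`
#'   (default 12.5 percent, generous for F6 lines whose expectation is ~3 percent).
#' @return list with elements `geno` (the filtered `geno_matrix`) and
#'   `report` (a `qc_report`).
#' @export
qc_filter <- function(g, maf_min = 0.01, max_missing = 0.05,
                      line_max_missing = 0.20, line_max_het = 0.125) {
  stopifnot(inherits(g, "geno_matrix"))
  if (g$coding != "minor")
    stop("qc_filter expects a minor-allele recoded matrix; run recode_minor_allele() first")
  dosage <- g$dosage
  n_lines_in <- nrow(dosage)
  n_markers_in <- ncol(dosage)

  line_miss <- rowMeans(is.na(dosage))
  line_het <- rowMeans(dosage == 1, na.rm = TRUE)
  drop_line <- line_miss > line_max_missing | line_het > line_max_het
  drop_line[is.na(drop_line)] <- TRUE
  lines_removed <- rownames(dosage)[drop_line]
  dosage <- dosage[!drop_line, , drop = FALSE]
  if (nrow(dosage) == 0L)
    stop("qc_filter: no lines left after line-level filtering")

  m <- maf(dosage)
  miss <- colMeans(is.na(dosage))
  keep_maf <- m > maf_min
  keep_miss <- miss < max_missing
  n_maf <- sum(!keep_maf)
  n_miss <- sum(keep_maf & !keep_miss)
  keep <- keep_maf & keep_miss
  dosage <- dosage[, keep, drop = FALSE]

  # duplicates: identical dosage vectors including missingness pattern;
  # the representative kept is the smallest marker id, so the retained set
  # does not depend on column order
  n_dup <- 0L
  if (ncol(dosage) > 1L) {
    key <- apply(dosage, 2, paste, collapse = "\r")
    ord <- order(colnames(dosage))
    keep_names <- colnames(dosage)[ord][!duplicated(key[ord])]
    n_dup <- ncol(dosage) - length(keep_names)
    dosage <- dosage[, colnames(dosage) %in% keep_names, drop = FALSE]
  }
  if (ncol(dosage) == 0L)
    stop("qc_filter: no markers left after filtering")

  out <- geno_matrix(
    dosage,
    map = g$map[match(colnames(dosage), g$map$marker), , drop = FALSE],
    lines = g$lines[match(rownames(dosage), g$lines$line), , drop = FALSE],
    coding = "minor")
  report <- structure(list(
    n_lines_in = n_lines_in, n_markers_in = n_markers_in,
    lines_removed = lines_removed,
    markers_removed_maf = n_maf,
    markers_removed_missing = n_miss,
    duplicates = n_dup,
    n_lines_out = nrow(dosage), n_markers_out = ncol(dosage),
    mean_maf = mean(maf(dosage)),
    thresholds = list(maf_min = maf_min, max_missing = max_missing,
                      line_max_missing = line_max_missing,
                      line_max_het = line_max_het)),
    class = "qc_report")
  list(geno = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC report\n")
  cat(sprintf("  lines:   %d in, %d removed (missing/heterogeneity), %d retained\n",
              x$n_lines_in, length(x$lines_removed), x$n_lines_out))
  cat(sprintf("  markers: %d in, %d removed (MAF <= %.3g), %d removed (missing >= %.3g), %d duplicates, %d retained\n",
              x$n_markers_in, x$markers_removed_maf, x$thresholds$maf_min,
              x$markers_removed_missing, x$thresholds$max_missing,
              x$duplicates, x$n_markers_out))
  cat(sprintf("  mean MAF of retained markers: %.3f\n", x$mean_maf))
  invisible(x)
}

#' Impute missing genotype calls
#'
#' Fills each missing call by a draw from Binomial(2, p) with p the marker's
#' observed counted-allele frequency. Deterministic for a fixed seed.
#'
#' @param g a [geno_matrix()] (typically post-QC).
#' @param seed integer seed.
#' @return a complete `geno_matrix`.
#' @export
impute_missing <- function(g, seed = 1L) {
  stopifnot(inherits(g, "geno_matrix"))
  dosage <- g$dosage
  if (!anyNA(dosage)) return(g)
  all_missing <- colSums(!is.na(dosage)) == 0L
  if (any(all_missing))
    stop("impute_missing: marker(s) with all calls missing: ",
         paste(colnames(dosage)[all_missing][seq_len(min(5, sum(all_missing)))],
               collapse = ", "))
  p <- marker_freq(dosage)
  with_seed(seed, {
    for (j in which(colSums(is.na(dosage)) > 0L)) {
      idx <- which(is.na(dosage[, j]))
      dosage[idx, j] <- stats::rbinom(length(idx), 2L, p[j])
    }
  })
  geno_matrix(dosage, map = g$map, lines = g$lines, coding = g$coding)
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
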