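#' Genotype matrix container
#'
#' Bundles a lines x markers dosage matrix with its marker map and line
#' metadata. Dosages count copies of one allele per marker: 0 and 2 are the
#' two homozygotes, 1 the heterozygote, `NA` a missing call. After
#' [recode_minor_allele()] the counted allele is the minor allele at every
#' marker (`coding = "minor"`).
#'
#' @param dosage numeric matrix, lines in rows (rownames = line ids), markers
#'   in columns (colnames = marker ids); values in 0, 1, 2 or NA.
#' @param map optional data.frame with columns `marker`, `chrom`, `pos`
#'   (positions are carried as annotation only). Defaults to a minimal map
#'   built from the column names.
#' @param lines optional data.frame with columns `line`, `program`, `set`
#'   (set is the season-membership label, e.g. CS / VS15 / VS16).
#' @param coding `"raw"` (arbitrary allele orientation) or `"minor"`
#'   (minor-allele dosage at every marker).
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, map = NULL, lines = NULL,
                        coding = c("raw", "minor")) {
  coding <- match.arg(coding)
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("L%04d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("M%05d", seq_len(ncol(dosage)))
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("dosage values must be 0, 1, 2 or NA")
  if (anyDuplicated(rownames(dosage)))
    stop("line ids must be unique")
  if (anyDuplicated(colnames(dosage)))
    stop("marker ids must be unique")
  if (is.null(map)) {
    map <- data.frame(marker = colnames(dosage), chrom = NA_character_,
                      pos = NA_real_, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("marker", "chrom", "pos") %in% names(map)))
  if (!identical(as.character(map$marker), colnames(dosage)))
    stop("map$marker must match dosage column names in order")
  if (is.null(lines)) {
    lines <- data.frame(line = rownames(dosage), program = NA_character_,
                        set = NA_character_, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("line", "program", "set") %in% names(lines)))
  if (!identical(as.character(lines$line), rownames(dosage)))
    stop("lines$line must match dosage row names in order")
  structure(list(dosage = dosage, map = map, lines = lines, coding = coding),
            class = "geno_matrix")
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' @export
print.geno_matrix <- function(x, ...) {
  d <- dim(x$dosage)
  miss <- mean(is.na(x$dosage))
  cat(sprintf("geno_matrix: %d lines x %d markers (%s coding, %.2f%% missing)\n",
              d[1], d[2], x$coding, 100 * miss))
  progs <- unique(x$lines$program)
  if (!all(is.na(progs)))
    cat("programs:", paste(progs, collapse = ", "), "\n")
  sets <- table(x$lines$set, useNA = "no")
  if (length(sets))
    cat("sets:", paste(names(sets), sets, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x a [geno_matrix()].
#' @param i line selector (ids, indices or logical).
#' @param j marker selector.
#' @param ... ignored.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  dos <- x$dosage[i, j, drop = FALSE]
  geno_matrix(dos,
              map = x$map[match(colnames(dos), x$map$marker), , drop = FALSE],
              lines = x$lines[match(rownames(dos), x$lines$line), , drop = FALSE],
              coding = x$coding)
}

# per-marker allele frequency of the counted allele, missing calls ignored
marker_freq <- function(dosage) colMeans(dosage, na.rm = TRUE) / 2

#' Minor allele frequency per marker
#'
#' Computed on non-missing calls; equals the frequency of the rarer allele
#' regardless of coding orientation.
#'
#' @param g a [geno_matrix()] or dosage matrix.
#' @return named numeric vector of MAFs.
#' @export
maf <- function(g) {
  dosage <- if (inherits(g, "geno_matrix")) g$dosage else as.matrix(g)
  p <- marker_freq(dosage)
  pmin(p, 1 - p)
}

#' Recode a genotype matrix to minor-allele dosages
#'
#' Flips every marker whose counted-allele frequency exceeds 0.5 so that
#' 0 = homozygous major, 1 = heterozygous, 2 = homozygous minor.
#' Idempotent: applying it twice equals applying it once.
#'
#' @param g a [geno_matrix()].
#' @return the recoded `geno_matrix` with `coding = "minor"`.
#' @export
recode_minor_allele <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  dosage <- g$dosage
  p <- marker_freq(dosage)
  flip <- which(p > 0.5)
  if (length(flip))
    dosage[, flip] <- 2 - dosage[, flip]
  geno_matrix(dosage, map = g$map, lines = g$lines, coding = "minor")
}
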