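#' Read a tab-delimited dosage table
#'
#' Expects lines in rows (first column `line`), markers in columns, dosage
#' codes 0/1/2 with `NA` for missing. Optional companion files give the
#' marker map and line metadata.
#'
#' @param file path to the tab-delimited dosage table.
#' @param map_file optional TSV with columns marker, chrom, pos.
#' @param lines_file optional TSV with columns line, program, set.
#' @param coding coding flag to record, `"raw"` or `"minor"`.
#' @return a [geno_matrix()].
#' @export
read_dosage_table <- function(file, map_file = NULL, lines_file = NULL,
                              coding = "raw") {
  tab <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  dosage <- as.matrix(tab[, -1, drop = FALSE])
  rownames(dosage) <- as.character(tab[[1]])
  storage.mode(dosage) <- "double"
  map <- if (!is.null(map_file))
    utils::read.delim(map_file, stringsAsFactors = FALSE) else NULL
  lines <- if (!is.null(lines_file))
    utils::read.delim(lines_file, stringsAsFactors = FALSE) else NULL
  geno_matrix(dosage, map = map, lines = lines, coding = coding)
}

#' Write a genotype matrix as a tab-delimited dosage table
#'
#' @param g a [geno_matrix()].
#' @param file output path; companion `<file>.map.tsv` and `<file>.lines.tsv`
#'   are written alongside when `with_metadata = TRUE`.
#' @param with_metadata also write map and line metadata files.
#' @return `file`, invisibly.
#' @export
write_dosage_table <- function(g, file, with_metadata = TRUE) {
  stopifnot(inherits(g, "geno_matrix"))
  tab <- data.frame(line = rownames(g$dosage), g$dosage,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (with_metadata) {
    utils::write.table(g$map, paste0(file, ".map.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(g$lines, paste0(file, ".lines.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Uses vcfR to parse the GT field; genotypes are converted to counts of the
#' ALT allele (0/0 -> 0, 0/1 or 1/0 -> 1, 1/1 -> 2, missing -> NA). Markers
#' with more than one ALT allele are rejected.
#'
#' @param file path to an (uncompressed or gzipped) VCF.
#' @param lines_file optional TSV with columns line, program, set.
#' @return a [geno_matrix()] with `coding = "raw"`.
#' @export
read_genotypes_vcf <- function(file, lines_file = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_genotypes_vcf requires the vcfR package")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE)))
    stop("multiallelic sites present; only biallelic SNPs are supported")
  gt <- vcfR::extract.gt(v, element = "GT")
  conv <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    out <- rep(NA_real_, length(x))
    out[x %in% "0/0"] <- 0
    out[x %in% c("0/1", "1/0")] <- 1
    out[x %in% "1/1"] <- 2
    out
  }
  dosage <- t(apply(gt, 2, conv))
  dimnames(dosage) <- list(colnames(gt), rownames(gt))
  map <- data.frame(marker = rownames(gt),
                    chrom = unname(fix[, "CHROM"]),
                    pos = as.numeric(fix[, "POS"]),
                    stringsAsFactors = FALSE)
  lines <- if (!is.null(lines_file))
    utils::read.delim(lines_file, stringsAsFactors = FALSE) else NULL
  geno_matrix(dosage, map = map, lines = lines, coding = "raw")
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits an uncompressed VCFv4.2 text file with GT calls only. Dosages are
#' written as counts of the ALT allele (0 -> 0/0, 1 -> 0/1, 2 -> 1/1,
#' NA -> ./.); REF/ALT are placeholder A/B alleles since the simulator does
#' not model nucleotides.
#'
#' @param g a [geno_matrix()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_genotypes_vcf <- function(g, file) {
  stopifnot(inherits(g, "geno_matrix"))
  dosage <- g$dosage
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=phsgp",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(dosage)), collapse = "\t")),
             con)
  chrom <- ifelse(is.na(g$map$chrom), "un", as.character(g$map$chrom))
  pos <- ifelse(is.na(g$map$pos), seq_len(ncol(dosage)), g$map$pos)
  for (j in seq_len(ncol(dosage))) {
    calls <- gt_code[as.character(dosage[, j])]
    calls[is.na(calls)] <- "./."
    writeLines(paste(c(chrom[j], format(pos[j], scientific = FALSE),
                       colnames(dosage)[j], "A", "B", ".", "PASS", ".", "GT",
                       calls), collapse = "\t"), con)
  }
  invisible(file)
}

#' Write a relationship matrix as square CSV with line-id header
#'
#' @param A a [vanraden_grm()] result (or any square matrix with dimnames).
#' @param file output path.
#' @export
write_grm_csv <- function(A, file) {
  utils::write.csv(data.frame(line = rownames(A), unclass(A)[, , drop = FALSE],
                              check.names = FALSE),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a QC report as CSV
#'
#' @param report a `qc_report` from [qc_filter()].
#' @param file output path.
#' @export
write_qc_report <- function(report, file) {
  stopifnot(inherits(report, "qc_report"))
  df <- data.frame(
    metric = c("n_lines_in", "n_lines_removed", "n_lines_out",
               "n_markers_in", "markers_removed_maf",
               "markers_removed_missing", "duplicates", "n_markers_out",
               "mean_maf"),
    value = c(report$n_lines_in, length(report$lines_removed),
              report$n_lines_out, report$n_markers_in,
              report$markers_removed_maf, report$markers_removed_missing,
              report$duplicates, report$n_markers_out,
              round(report$mean_maf, 4)))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read plot-level phenotype records
#'
#' @param file CSV with columns line, season, location, block, trait, value.
#' @return data.frame of records.
#' @export
read_phenotypes_csv <- function(file) {
  ph <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("line", "season", "location", "block", "trait", "value")
  if (!all(need %in% names(ph)))
    stop("phenotype CSV must have columns: ", paste(need, collapse = ", "))
  ph
}

#' Write plot-level phenotype records
#'
#' @param pheno data.frame with columns line, season, location, block,
#'   trait, value.
#' @param file output path.
#' @export
write_phenotypes_csv <- function(pheno, file) {
  utils::write.csv(pheno, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
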