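#' Germination index
#'
#' Weighted germination score over a fixed counting window: seeds that
#' germinate on day 1 get the maximum weight and the weight declines linearly
#' to 1 on the last day,
#' \deqn{GI = \frac{\sum_{d=1}^{D} (D - d + 1)\, n_d}{D\, n_{total}},}
#' so GI is 1 when every seed germinates on day 1 and 0 when none germinate.
#' Moving any germination event one day earlier never decreases GI.
#'
#' @param counts integer vector of daily germination counts (day 1 first).
#' @param n_total number of seeds plated; must be >= `sum(counts)`.
#' @param n_days counting window D; defaults to `length(counts)`.
#' @return GI in \[0, 1\].
#' @export
germination_index <- function(counts, n_total, n_days = length(counts)) {
  if (any(counts < 0)) stop("negative counts")
  stopifnot(n_days >= 1, length(counts) == n_days)
  if (sum(counts) > n_total)
    stop("sum of daily counts exceeds n_total")
  sum((n_days - seq_len(n_days) + 1) * counts) / (n_days * n_total)
}

new_var_decomp <- function(components, ratio_name, ratio, n_locations = NA_integer_,
                           converged = TRUE, logLik = NA_real_,
                           clamped = FALSE, note = NULL) {
  structure(list(components = components, ratio_name = ratio_name,
                 ratio = ratio, n_locations = n_locations,
                 converged = converged, logLik = logLik,
                 clamped = clamped, note = note),
            class = "var_decomp")
}

#' @export
print.var_decomp <- function(x, ...) {
  cat(sprintf("%s = %.3f%s\n", x$ratio_name, x$ratio,
              if (x$clamped) " (clamped to [0,1])" else ""))
  comps <- x$components
  cat("variance components:\n")
  for (nm in names(comps)) cat(sprintf("  %-14s %.4f\n", nm, comps[nm]))
  if (!is.na(x$n_locations)) cat("locations:", x$n_locations, "\n")
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

clamp01 <- function(x) {
  clamped <- x < 0 || x > 1
  list(value = min(max(x, 0), 1), clamped = clamped)
}

subset_pheno <- function(pheno, trait, season = NULL, location = NULL) {
  keep <- pheno$trait == trait
  if (!is.null(season)) keep <- keep & pheno$season == season
  if (!is.null(location)) keep <- keep & pheno$location == location
  ph <- pheno[keep & !is.na(pheno$value), , drop = FALSE]
  if (!nrow(ph)) stop("no records for the requested trait/season/location")
  # canonical record order: estimates do not depend on how rows were stored
  ph[order(ph$location, ph$block, ph$line), , drop = FALSE]
}

fit_lmer_quiet <- function(formula, data, contrasts = NULL) {
  ctrl <- lme4::lmerControl(
    optimizer = "bobyqa", check.conv.singular = "ignore",
    optCtrl = list(rhoend = 1e-10))
  withCallingHandlers(
    suppressMessages(lme4::lmer(formula, data = data, REML = TRUE,
                                contrasts = contrasts, control = ctrl)),
    warning = function(w) invokeRestart("muffleWarning"))
}

vc_lookup <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  stats::setNames(vc$vcov, vc$grp)
}

#' Within-environment repeatability
#'
#' REML fit of the single-environment augmented-design model
#' `value ~ (1|line) + (1|block)` (entries and blocks random); repeatability
#' is the variance ratio \eqn{rep^2 = \sigma^2_{entry} / (\sigma^2_{entry} +
#' \sigma^2_e)}. The repeated checks provide the error degrees of freedom in
#' an otherwise unreplicated trial.
#'
#' @param pheno plot-level records (line, season, location, block, trait,
#'   value).
#' @param trait trait name.
#' @param season season label.
#' @param location location name.
#' @return a `var_decomp` with components sigma2_g, sigma2_block, sigma2_e
#'   and ratio rep2.
#' @export
repeatability <- function(pheno, trait, season, location) {
  ph <- subset_pheno(pheno, trait, season, location)
  reps <- table(ph$line)
  if (all(reps <= 1L))
    stop("repeatability not estimable: no line replicated across blocks")
  ph$line <- factor(ph$line)
  ph$block <- factor(ph$block)
  fit <- tryCatch(fit_lmer_quiet(value ~ (1 | line) + (1 | block), ph),
                  error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate data (e.g. zero residual variance): fixed-effects fallback
    lmf <- stats::lm(value ~ 0 + line + block, ph)
    s2e <- suppressWarnings(summary(lmf)$sigma^2)
    s2g <- stats::var(stats::coef(lmf)[grepl("^line", names(stats::coef(lmf)))])
    r <- clamp01(s2g / (s2g + s2e))
    return(new_var_decomp(c(sigma2_g = s2g, sigma2_block = NA, sigma2_e = s2e),
                          "rep2", r$value, n_locations = 1L, clamped = r$clamped,
                          note = "degenerate REML fit: fixed-effects fallback"))
  }
  vc <- vc_lookup(fit)
  s2g <- vc[["line"]]; s2b <- vc[["block"]]; s2e <- vc[["Residual"]]
  r <- clamp01(s2g / (s2g + s2e))
  new_var_decomp(c(sigma2_g = s2g, sigma2_block = s2b, sigma2_e = s2e),
                 "rep2", r$value, n_locations = 1L,
                 logLik = as.numeric(stats::logLik(fit)), clamped = r$clamped)
}

#' Across-location adjusted means (BLUEs)
#'
#' One adjusted mean per line for a season, from the model with genotype
#' fixed, location fixed (sum-to-zero contrasts, so line coefficients are
#' means at the average location), block-within-location random and
#' genotype-by-location random. Falls back to the fixed-effects least-squares
#' fit if the mixed model is degenerate (e.g. noise-free data).
#'
#' @param pheno plot-level records.
#' @param trait trait name.
#' @param season season label.
#' @param include_checks include check varieties in the returned means.
#' @return named numeric vector of adjusted means.
#' @export
adjusted_means <- function(pheno, trait, season, include_checks = TRUE) {
  ph <- subset_pheno(pheno, trait, season)
  L <- length(unique(ph$location))
  if (L < 2) stop("adjusted means require >= 2 locations")
  ph$line <- factor(ph$line)
  ph$location <- factor(ph$location)
  ph$blk <- factor(paste(ph$location, ph$block, sep = ":"))
  ctr <- list(location = "contr.sum")
  fit <- tryCatch(
    fit_lmer_quiet(value ~ 0 + line + location + (1 | blk) + (1 | line:location),
                   ph, contrasts = ctr),
    error = function(e) NULL)
  cf <- if (is.null(fit))
    stats::coef(stats::lm(value ~ 0 + line + location, ph, contrasts = ctr))
  else lme4::fixef(fit)
  is_line <- grepl("^line", names(cf)) & !grepl("location", names(cf))
  means <- cf[is_line]
  names(means) <- sub("^line", "", names(means))
  means
}

#' Across-location heritability
#'
#' All-random variant of the adjusted-means model:
#' `value ~ (1|line) + (1|location) + (1|location:block) + (1|line:location)`.
#' Heritability on an entry-mean basis with one unreplicated plot per
#' location,
#' \deqn{h^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{g \times loc}/L +
#' \sigma^2_e/L}}
#' with L the number of locations carrying the trait. With a single location
#' the model degenerates to [repeatability()] and the result is flagged.
#'
#' @param pheno plot-level records.
#' @param trait trait name.
#' @param season season label.
#' @return a `var_decomp` with ratio h2.
#' @export
heritability <- function(pheno, trait, season) {
  ph <- subset_pheno(pheno, trait, season)
  locs <- unique(ph$location)
  L <- length(locs)
  if (L < 2) {
    out <- repeatability(pheno, trait, season, locs[1])
    out$note <- "single location: falling back to repeatability"
    return(out)
  }
  ph$line <- factor(ph$line)
  ph$location <- factor(ph$location)
  ph$blk <- factor(paste(ph$location, ph$block, sep = ":"))
  fit <- tryCatch(
    fit_lmer_quiet(
      value ~ (1 | line) + (1 | location) + (1 | blk) + (1 | line:location), ph),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate data (e.g. zero residual variance): fixed-effects fallback
    lmf <- stats::lm(value ~ 0 + line + location, ph)
    s2e <- suppressWarnings(summary(lmf)$sigma^2)
    s2g <- stats::var(stats::coef(lmf)[grepl("^line", names(stats::coef(lmf)))])
    r <- clamp01(s2g / (s2g + s2e / L))
    return(new_var_decomp(c(sigma2_g = s2g, sigma2_gxl = 0, sigma2_loc = NA,
                            sigma2_block = NA, sigma2_e = s2e),
                          "h2", r$value, n_locations = L, clamped = r$clamped,
                          note = "degenerate REML fit: fixed-effects fallback"))
  }
  vc <- vc_lookup(fit)
  s2g <- vc[["line"]]; s2gl <- vc[["line:location"]]
  s2loc <- vc[["location"]]; s2b <- vc[["blk"]]; s2e <- vc[["Residual"]]
  r <- clamp01(s2g / (s2g + s2gl / L + s2e / L))
  new_var_decomp(c(sigma2_g = s2g, sigma2_gxl = s2gl, sigma2_loc = s2loc,
                   sigma2_block = s2b, sigma2_e = s2e),
                 "h2", r$value, n_locations = L,
                 logLik = as.numeric(stats::logLik(fit)), clamped = r$clamped)
}

#' Trial-statistics summary table
#'
#' Per-environment repeatability and per-season heritability for a set of
#' traits, in the layout of a season-by-trait report.
#'
#' @param pheno plot-level records.
#' @param traits trait names (default: all present).
#' @param seasons season labels (default: all present).
#' @return data.frame with columns season, environment ("(across)" for the
#'   heritability rows), trait, statistic (rep2/h2), value.
#' @export
trial_summary <- function(pheno, traits = NULL, seasons = NULL) {
  if (is.null(traits)) traits <- unique(pheno$trait)
  if (is.null(seasons)) seasons <- unique(pheno$season)
  out <- list()
  for (s in seasons) for (tr in traits) {
    sub <- pheno[pheno$season == s & pheno$trait == tr, , drop = FALSE]
    if (!nrow(sub)) next
    for (loc in unique(sub$location)) {
      rp <- tryCatch(repeatability(pheno, tr, s, loc), error = function(e) NULL)
      if (!is.null(rp))
        out[[length(out) + 1L]] <- data.frame(
          season = s, environment = loc, trait = tr, statistic = "rep2",
          value = rp$ratio, stringsAsFactors = FALSE)
    }
    h <- tryCatch(heritability(pheno, tr, s), error = function(e) NULL)
    if (!is.null(h))
      out[[length(out) + 1L]] <- data.frame(
        season = s, environment = "(across)", trait = tr, statistic = "h2",
        value = h$ratio, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
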