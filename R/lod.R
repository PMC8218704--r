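#' One point of a serial-dilution experiment
#'
#' @param dilution_factor Dilution of the mutant DNA relative to neat
#'   (1 = neat, 10 = 1:10, ... 10000 = 1:10,000). The wild-type background
#'   is held at constant concentration across the series.
#' @param mutant Replicate mutant-droplet counts (one per well).
#' @param wt Replicate wild-type-droplet counts; carried for allele-fraction
#'   context only, never used for detection.
#' @return A `dilution_point`.
#' @export
dilution_point <- function(dilution_factor, mutant, wt = rep(NA_integer_, length(mutant))) {
  if (dilution_factor < 1)
    ddctdna_error("dilution_factor must be >= 1", "ddctdna_validation_error")
  if (length(mutant) < 1 || any(mutant < 0, na.rm = TRUE))
    ddctdna_error("need at least one replicate with non-negative mutant count",
                  "ddctdna_validation_error")
  if (length(wt) != length(mutant))
    ddctdna_error("mutant and wt must have one entry per replicate",
                  "ddctdna_validation_error")
  structure(list(dilution_factor = dilution_factor,
                 mutant = as.integer(mutant), wt = as.integer(wt)),
            class = "dilution_point")
}

#' Limit of detection from a serial-dilution series
#'
#' The assay's limit of detection is defined operationally: the fractional
#' abundance (VAF) of the neat mutant sample divided by the LOWEST
#' detectable dilution — i.e. the largest dilution factor at which the
#' mutant is still detected. A dilution point is detectable when its
#' mutant droplets reach `detect_threshold` (default 2), with replicates
#' either pooled (counts summed before the rule; default) or judged
#' individually (`"any"`: one detectable replicate suffices).
#'
#' @param neat_af Fractional abundance of the undiluted mutant sample,
#'   in (0, 1].
#' @param series List of [dilution_point]s (any order).
#' @param detect_threshold Minimum mutant droplets for detection; default 2.
#' @param replicate_rule `"pooled"` (default) or `"any"`.
#' @return An `lod_result` with fields `neat_af`,
#'   `lowest_detectable_factor` and `lod` (fraction; `lod = neat_af /
#'   lowest_detectable_factor`).
#' @examples
#' series <- list(
#'   dilution_point(10, c(132, 132)), dilution_point(100, c(13, 13)),
#'   dilution_point(1000, c(1, 0)), dilution_point(10000, c(0, 0)))
#' compute_lod(0.793, series)  # lod 0.00793 (0.793%)
#' @export
compute_lod <- function(neat_af, series, detect_threshold = 2,
                        replicate_rule = c("pooled", "any")) {
  replicate_rule <- match.arg(replicate_rule)
  if (neat_af <= 0 || neat_af > 1)
    ddctdna_error("neat_af must lie in (0, 1]", "ddctdna_validation_error")
  if (length(series) == 0)
    ddctdna_error("dilution series is empty", "ddctdna_validation_error")
  stopifnot(all(vapply(series, inherits, logical(1), "dilution_point")))
  detectable <- vapply(series, function(pt) {
    if (replicate_rule == "pooled") sum(pt$mutant) >= detect_threshold
    else any(pt$mutant >= detect_threshold)
  }, logical(1))
  factors <- vapply(series, `[[`, numeric(1), "dilution_factor")
  if (!any(detectable))
    ddctdna_error("no dilution point (including neat, if present) is detectable",
                  "ddctdna_no_detection")
  lowest <- max(factors[detectable])
  structure(list(neat_af = neat_af,
                 lowest_detectable_factor = lowest,
                 lod = neat_af / lowest,
                 detect_threshold = detect_threshold,
                 replicate_rule = replicate_rule),
            class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf(
    "limit of detection: %.4g%% (neat VAF %.4g%% / deepest detectable dilution 1:%g; >=%d mutant droplets, %s replicates)\n",
    100 * x$lod, 100 * x$neat_af, x$lowest_detectable_factor,
    x$detect_threshold, x$replicate_rule))
  invisible(x)
}

#' Summarize limits of detection across an assay panel
#'
#' @param assays List of `lod_result` objects (or bare numeric LoDs as
#'   fractions).
#' @return Named numeric vector with `min`, `median`, `max` (fractions).
#' @export
summarize_lod_panel <- function(assays) {
  if (length(assays) == 0)
    ddctdna_error("no assays supplied", "ddctdna_validation_error")
  lods <- vapply(assays, function(a)
    if (inherits(a, "lod_result")) a$lod else as.numeric(a), numeric(1))
  c(min = min(lods), median = median(lods), max = max(lods))
}
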