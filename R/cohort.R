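#' Quantify one sample end-to-end
#'
#' Chains the per-sample quantification: allele fraction from droplet
#' counts, Poisson concentrations and biofluid back-calculation (when the
#' total droplet count and a [reaction_setup] are available), cfDNA mass
#' concentration, and the positivity call. Inputs that are absent
#' propagate as `NA` fields — never as zeros.
#'
#' When only `(n_mut, n_wt)` are known (as in published summary tables),
#' the result carries the count-ratio allele fraction and the positivity
#' call; concentrations stay `NA`.
#'
#' @param n_mut Mutant-channel positive droplets.
#' @param n_wt Wild-type-channel positive droplets.
#' @param n_total Accepted droplets (optional; needed for concentrations
#'   and for `af_mode = "poisson"`).
#' @param setup A [reaction_setup] (optional; needed for biofluid
#'   back-calculation). If `sample` carries a `biofluid_volume`, it
#'   overrides `setup$v_sample`.
#' @param sample Optional one-row [sample_sheet] record (or list) with
#'   `patient_id`, `assay_id`, `sample_type`, `biofluid_volume`,
#'   `time_point`.
#' @param af_mode `"count_ratio"` (default) or `"poisson"`.
#' @param positivity_threshold Minimum mutant droplets for a positive
#'   call; default 2.
#' @return A `quant_result`.
#' @examples
#' run_sample(10, 398)   # VAF 2.451%, positive
#' run_sample(1, 500)    # VAF reported, but negative (below 2 droplets)
#' @export
run_sample <- function(n_mut, n_wt, n_total = NULL, setup = NULL,
                       sample = NULL, af_mode = c("count_ratio", "poisson"),
                       positivity_threshold = 2) {
  af_mode <- match.arg(af_mode)
  id <- if (!is.null(sample) && !is.null(sample$patient_id))
    as.character(sample$patient_id) else NA_character_
  if (n_mut + n_wt == 0)
    ddctdna_error(sprintf(
      "sample %s: no positive droplets on either channel, allele fraction undefined",
      if (is.na(id)) "<unnamed>" else id), "ddctdna_undefined_fraction")
  af <- allele_fraction(n_mut, n_wt, n_total = n_total, mode = af_mode)

  c_mut <- c_wt <- c_mut_ori <- c_wt_ori <- NA_real_
  cfdna_mut <- cfdna_wt <- ccfdna <- NA_real_
  if (!is.null(n_total) && !is.null(setup)) {
    if (!is.null(sample) && !is.null(sample$biofluid_volume) &&
        !is.na(sample$biofluid_volume)) {
      setup <- reaction_setup(v_pcr = setup$v_pcr, v_elu = setup$v_elu,
                              v_dna_pcr = setup$v_dna_pcr,
                              v_sample = sample$biofluid_volume,
                              droplet_volume = setup$droplet_volume,
                              genome_mass = setup$genome_mass)
    }
    c_mut <- poisson_concentration(n_mut, n_total, setup$droplet_volume)
    c_wt <- poisson_concentration(n_wt, n_total, setup$droplet_volume)
    c_mut_ori <- back_calculate_original(c_mut, setup)
    c_wt_ori <- back_calculate_original(c_wt, setup)
    cfdna_mut <- setup$genome_mass * c_mut_ori
    cfdna_wt <- setup$genome_mass * c_wt_ori
    ccfdna <- cfdna_mass_concentration(c_mut_ori, c_wt_ori, setup$genome_mass)
  }
  structure(list(
    patient_id = id,
    assay_id = if (!is.null(sample$assay_id)) as.character(sample$assay_id) else NA_character_,
    sample_type = if (!is.null(sample$sample_type)) as.character(sample$sample_type) else NA_character_,
    biofluid_volume = if (!is.null(sample$biofluid_volume)) as.numeric(sample$biofluid_volume) else NA_real_,
    time_point = if (!is.null(sample$time_point)) as.character(sample$time_point) else NA_character_,
    mutant_droplets = as.integer(n_mut), wt_droplets = as.integer(n_wt),
    n_total = if (is.null(n_total)) NA_integer_ else as.integer(n_total),
    af = af, af_mode = af_mode,
    c_mut = c_mut, c_wt = c_wt,
    c_mut_ori = c_mut_ori, c_wt_ori = c_wt_ori,
    cfdna_mutant_ng_ml = cfdna_mut, cfdna_wt_ng_ml = cfdna_wt,
    ccfdna = ccfdna,
    positive = call_positivity(n_mut, positivity_threshold)),
    class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("ddPCR quantification%s\n",
              if (is.na(x$patient_id)) "" else sprintf(" [%s]", x$patient_id)))
  cat(sprintf("  VAF: %.3f%% (%s; %d mutant / %d wild-type droplets)\n",
              100 * x$af, x$af_mode, x$mutant_droplets, x$wt_droplets))
  if (!is.na(x$ccfdna))
    cat(sprintf("  cfDNA: %.3f ng/mL (mutant %.3f, wild-type %.3f)\n",
                x$ccfdna, x$cfdna_mutant_ng_ml, x$cfdna_wt_ng_ml))
  cat(sprintf("  call: %s\n", if (x$positive) "POSITIVE (>= 2 mutant droplets)"
              else "negative"))
  invisible(x)
}

#' Flatten quantification results into a data.frame
#'
#' @param results List of `quant_result` objects.
#' @return Data.frame, one row per result; `vaf_percent` is `100 * af`.
#' @export
results_table <- function(results) {
  if (inherits(results, "quant_result")) results <- list(results)
  if (length(results) == 0) {
    empty <- as.data.frame(setNames(
      rep(list(logical(0)), length(RESULT_COLUMNS)), RESULT_COLUMNS))
    return(empty)
  }
  rows <- lapply(results, function(r) data.frame(
    patient_id = r$patient_id, assay_id = r$assay_id,
    sample_type = r$sample_type, biofluid_volume = r$biofluid_volume,
    time_point = r$time_point,
    vaf_percent = 100 * r$af, mutant_droplets = r$mutant_droplets,
    wt_droplets = r$wt_droplets,
    cfdna_mutant_ng_ml = r$cfdna_mutant_ng_ml,
    cfdna_wt_ng_ml = r$cfdna_wt_ng_ml, ccfdna = r$ccfdna,
    positive = r$positive))
  do.call(rbind, rows)
}

# round-half-up to integer (printed positivity style: 26, 67, 33)
round_half_up <- function(x) floor(x + 0.5)

#' Summarize a cohort by biofluid
#'
#' Tallies assayed and positive samples per biofluid, with positivity as
#' an exact fraction and as an integer percent (round-half-up, the style
#' of printed cohort summaries). Volume and cfDNA-concentration
#' descriptive statistics are included when the columns are present.
#'
#' @param results Data.frame with one row per assayed sample, carrying at
#'   least `sample_type` and `positive` (e.g. [results_table] output
#'   joined to a sample sheet). Samples with no detectable signal count as
#'   negative rows.
#' @return A `cohort_summary`: data.frame with one row per biofluid plus a
#'   `total` row, and columns `n_assayed`, `n_positive`, `positivity`,
#'   `positivity_percent` (and volume / ccfdna statistics if available).
#' @export
summarize_cohort <- function(results) {
  if (!all(c("sample_type", "positive") %in% names(results)))
    ddctdna_error("results must be joined to sample records: need columns sample_type and positive",
                  "ddctdna_validation_error")
  if (anyNA(results$sample_type) || anyNA(results$positive))
    ddctdna_error("unjoined result: sample_type/positive contain NA",
                  "ddctdna_validation_error")
  fluids <- intersect(BIOFLUIDS, unique(results$sample_type))
  one <- function(df, label) {
    row <- data.frame(sample_type = label,
                      n_assayed = nrow(df),
                      n_positive = sum(df$positive),
                      positivity = if (nrow(df) > 0) sum(df$positive) / nrow(df) else 0)
    row$positivity_percent <- round_half_up(100 * row$positivity)
    for (col in c("biofluid_volume", "ccfdna")) {
      if (col %in% names(df)) {
        v <- df[[col]][!is.na(df[[col]])]
        row[[paste0(col, "_mean")]] <- if (length(v)) mean(v) else NA_real_
        row[[paste0(col, "_sd")]] <- if (length(v) > 1) sd(v) else NA_real_
        row[[paste0(col, "_median")]] <- if (length(v)) median(v) else NA_real_
      }
    }
    row
  }
  per_fluid <- do.call(rbind, lapply(fluids, function(f)
    one(results[results$sample_type == f, , drop = FALSE], f)))
  out <- rbind(per_fluid, one(results, "total"))
  structure(out, class = c("cohort_summary", "data.frame"))
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("cohort positivity by biofluid (>= 2 mutant droplets):\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-7s %d/%d (%d%%)\n", x$sample_type[i], x$n_positive[i],
                x$n_assayed[i], x$positivity_percent[i]))
  invisible(as.data.frame(x))
}

#' Longitudinal concentration series per patient
#'
#' Orders each patient's samples by time and emits a tidy table for
#' plotting cfDNA concentration against days from a reference date, with
#' optional clinical event annotations carried through.
#'
#' @param results Data.frame with columns `patient_id`, `time_point`,
#'   `days` (numeric days from the reference), `ccfdna`, and optionally
#'   `event`.
#' @return A `longitudinal_series`: the input sorted by `(patient_id,
#'   days)`, with time strictly increasing within each patient.
#' @export
build_longitudinal <- function(results) {
  need <- c("patient_id", "time_point", "days", "ccfdna")
  miss <- setdiff(need, names(results))
  if (length(miss) > 0)
    ddctdna_error(sprintf("longitudinal input is missing column(s): %s",
                          paste(miss, collapse = ", ")), "ddctdna_format_error")
  dup <- duplicated(results[, c("patient_id", "time_point")])
  if (any(dup)) {
    d <- results[dup, , drop = FALSE]
    ddctdna_error(sprintf("duplicate (patient, time-point) pair(s): %s",
                          paste(sprintf("%s@%s", d$patient_id, d$time_point),
                                collapse = ", ")), "ddctdna_validation_error")
  }
  out <- results[order(results$patient_id, results$days), , drop = FALSE]
  for (pid in unique(out$patient_id)) {
    dd <- out$days[out$patient_id == pid]
    if (any(diff(dd) <= 0))
      ddctdna_error(sprintf("non-increasing time within patient %s", pid),
                    "ddctdna_validation_error")
  }
  rownames(out) <- NULL
  structure(out, class = c("longitudinal_series", "data.frame"))
}

#' Bundled example cohort: pediatric high-grade glioma liquid biopsies
#'
#' A 43-sample feasibility cohort of liquid biopsies (27 plasma, 9 CSF, 6
#' serum, 1 cystic fluid) from pediatric high-grade glioma and DIPG
#' patients assayed by mutation-specific ddPCR. The 16 samples with
#' detectable ctDNA ship with their full droplet counts and per-channel
#' cfDNA concentrations; the remaining 27 rows are reconstructed from the
#' cohort composition (seven samples showed exactly one mutant droplet —
#' five plasma, two CSF — and the rest none), with wild-type counts
#' unknown (`NA`) for undetected samples.
#'
#' @return Data.frame with columns `patient_id`, `assay_id`,
#'   `sample_type`, `biofluid_volume`, `vaf_printed_percent`,
#'   `mutant_droplets`, `wt_droplets`, `cfdna_mutant_ng_ml`,
#'   `cfdna_wt_ng_ml`, `detected`.
#' @export
example_cohort <- function() {
  det <- read.delim(system.file("extdata", "detected_samples.tsv",
                                package = "ddctdna"), check.names = TRUE)
  comp <- read.delim(system.file("extdata", "cohort_composition.tsv",
                                 package = "ddctdna"), check.names = TRUE)
  det$detected <- TRUE
  rows <- list(det)
  for (i in seq_len(nrow(comp))) {
    fluid <- comp$sample_type[i]
    n_rest <- comp$n_assayed[i] - sum(det$sample_type == fluid)
    n_single <- comp$n_single_droplet[i]
    if (n_rest > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = sprintf("UND-%s-%02d", fluid, seq_len(n_rest)),
        assay_id = NA_character_, sample_type = fluid,
        biofluid_volume = NA_real_, vaf_printed_percent = NA_real_,
        mutant_droplets = c(rep(1L, n_single), rep(0L, n_rest - n_single)),
        wt_droplets = NA_integer_, cfdna_mutant_ng_ml = NA_real_,
        cfdna_wt_ng_ml = NA_real_, detected = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
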