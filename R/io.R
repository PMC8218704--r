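#' Read a two-channel droplet amplitude table
#'
#' Reads a per-well droplet amplitude export: one row per accepted droplet,
#' two fluorescence channels (channel 1 = mutant probe, FAM; channel 2 =
#' wild-type probe, VIC/HEX). The default dialect is the common instrument
#' CSV export: comma-separated, UTF-8, header row with columns
#' `"Ch1 Amplitude"` and `"Ch2 Amplitude"`; other headers can be mapped via
#' `columns`. A vendor cluster-label column, if named, is carried along.
#'
#' @param path Path to the CSV file.
#' @param columns Named character vector mapping internal names to file
#'   headers. Must contain `ch1` and `ch2`; may contain `cluster`.
#' @param well_id Optional well identifier attached to the result; defaults
#'   to the file name without extension.
#'
#' @return An `amplitude_table`: a data.frame with numeric columns `ch1`,
#'   `ch2` and optionally `cluster`, one row per droplet in file order,
#'   with attribute `well_id`.
#'
#' @details Rows are never silently dropped: any non-numeric or negative
#'   amplitude aborts with an error naming the offending data line.
#' @export
read_amplitude_table <- function(path,
                                 columns = c(ch1 = "Ch1 Amplitude",
                                             ch2 = "Ch2 Amplitude"),
                                 well_id = NULL) {
  if (!file.exists(path))
    ddctdna_error(sprintf("amplitude file not found: %s", path), "ddctdna_io_error")
  if (!all(c("ch1", "ch2") %in% names(columns)))
    ddctdna_error("`columns` must map both 'ch1' and 'ch2'", "ddctdna_format_error")
  raw <- read.csv(path, check.names = FALSE, colClasses = "character",
                  strip.white = TRUE)
  for (col in columns[c("ch1", "ch2")]) {
    if (!col %in% names(raw))
      ddctdna_error(sprintf("missing amplitude column '%s' in %s", col, path),
                    "ddctdna_format_error")
  }
  parse_channel <- function(col) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) | !is.finite(vals) | vals < 0)
    if (length(bad) > 0)
      ddctdna_error(sprintf(
        "non-numeric or negative amplitude in column '%s' at line %d of %s",
        col, bad[1] + 1L, path), "ddctdna_format_error")
    vals
  }
  out <- data.frame(ch1 = parse_channel(columns[["ch1"]]),
                    ch2 = parse_channel(columns[["ch2"]]))
  if ("cluster" %in% names(columns) && columns[["cluster"]] %in% names(raw))
    out$cluster <- raw[[columns[["cluster"]]]]
  if (is.null(well_id)) well_id <- sub("\\.[^.]*$", "", basename(path))
  amplitude_table(out, well_id = well_id)
}

#' Construct an amplitude table from amplitude vectors
#'
#' @param x Data.frame with numeric columns `ch1`, `ch2` (optionally
#'   `cluster`), one row per droplet.
#' @param well_id Well identifier.
#' @return An `amplitude_table`.
#' @export
amplitude_table <- function(x, well_id = "well") {
  stopifnot(is.data.frame(x), all(c("ch1", "ch2") %in% names(x)))
  if (nrow(x) > 0 &&
      (!all(is.finite(x$ch1)) || !all(is.finite(x$ch2)) ||
       any(x$ch1 < 0) || any(x$ch2 < 0)))
    ddctdna_error("amplitudes must be finite and non-negative", "ddctdna_format_error")
  structure(x, well_id = well_id, class = c("amplitude_table", "data.frame"))
}

#' Write an amplitude table in the dialect `read_amplitude_table` reads
#'
#' @param table An `amplitude_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_amplitude_table <- function(table, path) {
  out <- data.frame(`Ch1 Amplitude` = table$ch1,
                    `Ch2 Amplitude` = table$ch2,
                    check.names = FALSE)
  if (!is.null(table$cluster)) out$Cluster <- table$cluster
  write.csv_safe(out, path)
  invisible(path)
}

# write.csv without row names, erroring on unwritable paths
write.csv_safe <- function(df, path) {
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    ddctdna_error(sprintf("cannot write %s: %s", path, conditionMessage(ok)),
                  "ddctdna_io_error")
}

BIOFLUIDS <- c("plasma", "serum", "CSF", "cyst")

#' Read a sample sheet
#'
#' Tab-separated sheet describing the biological samples: columns
#' `patient_id`, `assay_id`, `sample_type`, `biofluid_volume` (mL used for
#' cfDNA extraction) and optional `time_point`. `sample_type` is matched
#' case-insensitively against the closed set plasma / serum / CSF / cyst
#' and normalized.
#'
#' @param path Path to the TSV file.
#' @return A `sample_sheet`: a validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path))
    ddctdna_error(sprintf("sample sheet not found: %s", path), "ddctdna_io_error")
  raw <- read.delim(path, check.names = TRUE, colClasses = "character",
                    strip.white = TRUE)
  sample_sheet(raw)
}

#' Construct and validate a sample sheet
#'
#' @param x Data.frame with columns `patient_id`, `assay_id`, `sample_type`,
#'   `biofluid_volume`, optionally `time_point`.
#' @return A `sample_sheet`.
#' @export
sample_sheet <- function(x) {
  need <- c("patient_id", "assay_id", "sample_type", "biofluid_volume")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    ddctdna_error(sprintf("sample sheet is missing column(s): %s",
                          paste(miss, collapse = ", ")), "ddctdna_format_error")
  idx <- match(tolower(x$sample_type), tolower(BIOFLUIDS))
  if (anyNA(idx))
    ddctdna_error(sprintf(
      "unknown sample_type '%s'; allowed values: %s",
      x$sample_type[which(is.na(idx))[1]], paste(BIOFLUIDS, collapse = ", ")),
      "ddctdna_validation_error")
  x$sample_type <- BIOFLUIDS[idx]
  vol <- suppressWarnings(as.numeric(x$biofluid_volume))
  if (anyNA(vol) || any(vol <= 0))
    ddctdna_error("biofluid_volume must be a positive number for every sample",
                  "ddctdna_validation_error")
  x$biofluid_volume <- vol
  if (is.null(x$time_point)) x$time_point <- NA_character_
  structure(x, class = c("sample_sheet", "data.frame"))
}

# column order of the results table; mirrors the per-sample summary layout
# (VAF in percent, droplet tallies, per-channel cfDNA mass concentration)
RESULT_COLUMNS <- c("patient_id", "assay_id", "sample_type", "biofluid_volume",
                    "vaf_percent", "mutant_droplets", "wt_droplets",
                    "cfdna_mutant_ng_ml", "cfdna_wt_ng_ml", "positive")

#' Write quantification results to a TSV
#'
#' Serializes a list of [quant_result] objects (or the data.frame from
#' [results_table]) with a fixed column order. VAF (percent) and ng/mL
#' concentrations are written with 3 decimals, matching the conventional
#' reporting precision of ddPCR liquid-biopsy tables.
#'
#' @param results List of `quant_result` objects or a data.frame from
#'   [results_table].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  df <- if (is.data.frame(results)) results else results_table(results)
  for (col in setdiff(RESULT_COLUMNS, names(df))) df[[col]] <- NA
  df <- df[, RESULT_COLUMNS, drop = FALSE]
  fmt3 <- function(v) ifelse(is.na(v), "NA", formatC(v, format = "f", digits = 3))
  df$vaf_percent <- fmt3(df$vaf_percent)
  df$cfdna_mutant_ng_ml <- fmt3(df$cfdna_mutant_ng_ml)
  df$cfdna_wt_ng_ml <- fmt3(df$cfdna_wt_ng_ml)
  ok <- tryCatch({
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    ddctdna_error(sprintf("cannot write %s: %s", path, conditionMessage(ok)),
                  "ddctdna_io_error")
  invisible(path)
}

#' Read back a results TSV written by [write_results]
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the fixed result columns; numerics parsed.
#' @export
read_results <- function(path) {
  if (!file.exists(path))
    ddctdna_error(sprintf("results file not found: %s", path), "ddctdna_io_error")
  df <- read.delim(path, check.names = TRUE, na.strings = "NA")
  num <- c("biofluid_volume", "vaf_percent", "mutant_droplets", "wt_droplets",
           "cfdna_mutant_ng_ml", "cfdna_wt_ng_ml")
  for (col in intersect(num, names(df))) df[[col]] <- as.numeric(df[[col]])
  if ("positive" %in% names(df)) df$positive <- as.logical(df$positive)
  df
}
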