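#' Classification thresholds for two-channel droplet amplitudes
#'
#' @param ch1_cutoff Channel-1 (mutant/FAM) fluorescence cutoff.
#' @param ch2_cutoff Channel-2 (wild-type/VIC-HEX) fluorescence cutoff.
#' @param method `"fixed"` for user-set cutoffs, `"control-derived"` when
#'   estimated from control wells.
#' @param separation_warning Logical flag set by [estimate_thresholds] when
#'   a cutoff does not fall below the positive-control cluster mean.
#' @return A `classification_thresholds` object.
#' @export
classification_thresholds <- function(ch1_cutoff, ch2_cutoff,
                                      method = c("fixed", "control-derived"),
                                      separation_warning = FALSE) {
  method <- match.arg(method)
  cuts <- c(ch1_cutoff, ch2_cutoff)
  if (length(cuts) != 2 || !all(is.finite(cuts)) || any(cuts <= 0))
    ddctdna_error("cutoffs must be strictly positive finite scalars",
                  "ddctdna_validation_error")
  structure(list(ch1_cutoff = ch1_cutoff, ch2_cutoff = ch2_cutoff,
                 method = method, separation_warning = separation_warning),
            class = "classification_thresholds")
}

#' @export
print.classification_thresholds <- function(x, ...) {
  cat(sprintf("droplet classification thresholds (%s): ch1 > %g, ch2 > %g\n",
              x$method, x$ch1_cutoff, x$ch2_cutoff))
  if (isTRUE(x$separation_warning))
    cat("  WARNING: cutoff not below positive-control cluster mean\n")
  invisible(x)
}

#' Classified droplet tallies for one well
#'
#' Channel totals follow the duplex ddPCR convention: `n_mut` and `n_wt`
#' each INCLUDE the double positives, so `n_empty = n_total - (n_mut +
#' n_wt - n_double)`.
#'
#' @param n_total Accepted droplets in the well.
#' @param n_mut Droplets positive in the mutant channel (incl. doubles).
#' @param n_wt Droplets positive in the wild-type channel (incl. doubles).
#' @param n_double Droplets positive in both channels.
#' @return A `well_counts` object.
#' @export
well_counts <- function(n_total, n_mut, n_wt, n_double) {
  v <- c(n_total, n_mut, n_wt, n_double)
  if (any(v < 0) || any(v != round(v)))
    ddctdna_error("droplet tallies must be non-negative integers",
                  "ddctdna_validation_error")
  if (n_double > min(n_mut, n_wt) || max(n_mut, n_wt) > n_total)
    ddctdna_error("inconsistent tallies: need n_double <= min(n_mut, n_wt) and channel totals <= n_total",
                  "ddctdna_validation_error")
  n_empty <- n_total - (n_mut + n_wt - n_double)
  if (n_empty < 0)
    ddctdna_error("inconsistent tallies: implied empty-droplet count is negative",
                  "ddctdna_validation_error")
  structure(list(n_total = as.integer(n_total), n_mut = as.integer(n_mut),
                 n_wt = as.integer(n_wt), n_double = as.integer(n_double),
                 n_empty = as.integer(n_empty)),
            class = "well_counts")
}

#' @export
print.well_counts <- function(x, ...) {
  cat(sprintf(
    "well counts: %d accepted | mutant+ %d, wild-type+ %d (double %d), empty %d\n",
    x$n_total, x$n_mut, x$n_wt, x$n_double, x$n_empty))
  invisible(x)
}

#' Classify droplets into mutant / wild-type / double / empty
#'
#' A droplet is mutant-channel positive iff its channel-1 amplitude is
#' strictly above `ch1_cutoff`, wild-type-channel positive iff channel 2 is
#' strictly above `ch2_cutoff`, double positive iff both. Ties at the
#' cutoff count as negative.
#'
#' @param table An [amplitude_table].
#' @param thresholds A [classification_thresholds].
#' @return A [well_counts].
#' @export
classify_droplets <- function(table, thresholds) {
  stopifnot(inherits(thresholds, "classification_thresholds"))
  pos1 <- table$ch1 > thresholds$ch1_cutoff
  pos2 <- table$ch2 > thresholds$ch2_cutoff
  well_counts(n_total = nrow(table),
              n_mut = sum(pos1),
              n_wt = sum(pos2),
              n_double = sum(pos1 & pos2))
}

#' Per-droplet class labels under a threshold pair
#'
#' @inheritParams classify_droplets
#' @return Character vector over `{"empty","mutant","wild_type","double"}`,
#'   one label per droplet in row order.
#' @export
droplet_labels <- function(table, thresholds) {
  pos1 <- table$ch1 > thresholds$ch1_cutoff
  pos2 <- table$ch2 > thresholds$ch2_cutoff
  out <- rep("empty", nrow(table))
  out[pos1 & !pos2] <- "mutant"
  out[!pos1 & pos2] <- "wild_type"
  out[pos1 & pos2] <- "double"
  out
}

#' Derive classification thresholds from control wells
#'
#' Per channel, the cutoff is `mean + k * SD` of the negative-control
#' amplitudes (k-sigma rule, default k = 5). The positive control is used
#' only as a sanity check: if a cutoff does not fall below the
#' positive-control cluster mean on its channel, the result carries a
#' separation warning (and a condition of class
#' `ddctdna_separation_warning` is signalled).
#'
#' @param negative_control [amplitude_table] of a non-template or
#'   wild-type-only control well; at least 50 droplets.
#' @param positive_control [amplitude_table] of a positive control well.
#' @param k Multiplier on the negative-control SD; default 5.
#' @return A [classification_thresholds] with `method = "control-derived"`.
#' @export
estimate_thresholds <- function(negative_control, positive_control, k = 5) {
  if (nrow(negative_control) < 50)
    ddctdna_error("negative control must contain at least 50 droplets",
                  "ddctdna_validation_error")
  sds <- c(sd(negative_control$ch1), sd(negative_control$ch2))
  if (any(sds == 0) || anyNA(sds))
    ddctdna_error("degenerate negative control: zero amplitude variance",
                  "ddctdna_validation_error")
  cut1 <- mean(negative_control$ch1) + k * sds[1]
  cut2 <- mean(negative_control$ch2) + k * sds[2]
  warn <- cut1 >= mean(positive_control$ch1) || cut2 >= mean(positive_control$ch2)
  if (warn)
    warning(structure(
      class = c("ddctdna_separation_warning", "warning", "condition"),
      list(message = "cutoff at or above positive-control cluster mean: poor cluster separation",
           call = sys.call(-1))))
  classification_thresholds(cut1, cut2, method = "control-derived",
                            separation_warning = warn)
}
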