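#' Absolute concentration by Poisson inversion of droplet counts
#'
#' Digital PCR counts partitions, not molecules: a droplet is positive if
#' it received at least one template copy, so the positive fraction p
#' estimates the mean occupancy lambda through p = 1 - exp(-lambda).
#' Inverting, lambda = -log(1 - p), and the concentration of the PCR mix
#' is lambda per droplet volume.
#'
#' @param n_positive Positive droplets on the channel.
#' @param n_total Accepted droplets.
#' @param droplet_volume Droplet volume in nL (default 0.85).
#' @return Concentration in copies/uL of PCR mix.
#' @examples
#' poisson_concentration(1500, 15000)  # -log(0.9)/0.00085 ~ 123.95
#' @export
poisson_concentration <- function(n_positive, n_total, droplet_volume = 0.85) {
  if (length(n_total) != 1 || n_total <= 0)
    ddctdna_error("n_total must be a positive droplet count", "ddctdna_validation_error")
  if (droplet_volume <= 0)
    ddctdna_error("droplet_volume must be positive", "ddctdna_validation_error")
  if (any(n_positive < 0) || any(n_positive > n_total))
    ddctdna_error("need 0 <= n_positive <= n_total", "ddctdna_validation_error")
  if (any(n_positive == n_total))
    ddctdna_error("all droplets positive: reaction saturated, concentration unbounded",
                  "ddctdna_saturation_error")
  lambda <- -log(1 - n_positive / n_total)
  lambda / (droplet_volume / 1000)  # nL -> uL
}

#' Mutant allele fraction from droplet counts
#'
#' Two estimators are provided. `count_ratio` is the raw droplet-count
#' quotient n_mut / (n_mut + n_wt) — the convention of published ddPCR
#' liquid-biopsy tables. `poisson` converts each channel's positive count
#' to an occupancy lambda first and returns lambda_mut / (lambda_mut +
#' lambda_wt); this corrects for multiply occupied droplets and is
#' preferable above ~5% channel occupancy, where the raw quotient starts
#' to overstate the minor allele. Below that occupancy the two agree to
#' about 1e-3 absolute.
#'
#' @param n_mut Mutant-channel positive droplets (incl. doubles).
#' @param n_wt Wild-type-channel positive droplets (incl. doubles).
#' @param n_total Accepted droplets; required for `mode = "poisson"`.
#' @param mode `"count_ratio"` (default) or `"poisson"`.
#' @return Allele fraction in `[0, 1]`.
#' @examples
#' allele_fraction(10, 398)            # 0.02451 (2.451%)
#' allele_fraction(3945, 4050)         # 0.49343
#' @export
allele_fraction <- function(n_mut, n_wt, n_total = NULL,
                            mode = c("count_ratio", "poisson")) {
  mode <- match.arg(mode)
  if (any(c(n_mut, n_wt) < 0))
    ddctdna_error("droplet counts must be non-negative", "ddctdna_validation_error")
  if (n_mut + n_wt == 0)
    ddctdna_error("no positive droplets on either channel: allele fraction undefined",
                  "ddctdna_undefined_fraction")
  if (mode == "count_ratio") return(n_mut / (n_mut + n_wt))
  if (is.null(n_total))
    ddctdna_error("poisson mode requires n_total", "ddctdna_validation_error")
  # droplet volume cancels in the ratio; any positive value works
  lm <- poisson_concentration(n_mut, n_total, droplet_volume = 1)
  lw <- poisson_concentration(n_wt, n_total, droplet_volume = 1)
  lm / (lm + lw)
}

#' Back-calculate a concentration to the original biofluid
#'
#' Converts copies/uL of PCR mix to copies/mL of the biofluid the DNA was
#' extracted from. Total copies in the reaction are `v_pcr * c`; scaling
#' by `v_elu / v_dna_pcr` recovers the copies in the full eluate (assuming
#' homogeneous eluate), and dividing by `v_sample` (mL) yields copies per
#' mL of biofluid. Applies identically to the mutant and wild-type
#' channels.
#'
#' @param c Concentration in copies/uL of PCR mix.
#' @param setup A [reaction_setup].
#' @return Concentration in copies/mL of original biofluid.
#' @examples
#' setup <- reaction_setup(v_pcr = 20, v_elu = 50, v_dna_pcr = 10, v_sample = 2)
#' back_calculate_original(5, setup)  # 250 copies/mL
#' @export
back_calculate_original <- function(c, setup) {
  stopifnot(is_reaction_setup(setup))
  if (any(c < 0))
    ddctdna_error("concentration must be non-negative", "ddctdna_validation_error")
  (setup$v_pcr * c * setup$v_elu) / (setup$v_dna_pcr * setup$v_sample)
}

#' Cell-free DNA mass concentration
#'
#' Converts allele concentrations in the biofluid (copies/mL) to a cfDNA
#' mass concentration (ng/mL) using the mass of one haploid human genome
#' (default 0.003 ng): each allele copy reports one haploid genome
#' equivalent.
#'
#' @param c_mut_ori Mutant allele copies/mL of biofluid.
#' @param c_wt_ori Wild-type allele copies/mL of biofluid.
#' @param genome_mass ng per haploid genome (default 0.003).
#' @return cfDNA concentration in ng/mL.
#' @examples
#' cfdna_mass_concentration(1000, 9000)  # 30 ng/mL
#' @export
cfdna_mass_concentration <- function(c_mut_ori, c_wt_ori, genome_mass = 0.003) {
  if (any(c(c_mut_ori, c_wt_ori) < 0) || genome_mass <= 0)
    ddctdna_error("concentrations must be non-negative and genome_mass positive",
                  "ddctdna_validation_error")
  genome_mass * (c_mut_ori + c_wt_ori)
}

#' Sample positivity by the mutant-droplet rule
#'
#' A sample is called positive when it shows at least `threshold` mutant
#' droplets (default 2). A single mutant droplet is never sufficient: it
#' is indistinguishable from a rare false-positive event.
#'
#' @param mutant_droplets Mutant-positive droplet count.
#' @param threshold Minimum mutant droplets for a positive call; default 2.
#' @return Logical.
#' @export
call_positivity <- function(mutant_droplets, threshold = 2) {
  if (any(mutant_droplets < 0) || threshold < 0)
    ddctdna_error("counts must be non-negative", "ddctdna_validation_error")
  mutant_droplets >= threshold
}

#' Copy-number fold call from a target/reference duplex assay
#'
#' The fold is the raw ratio of target to reference concentration
#' (copies/uL). Amplification is called when the fold STRICTLY exceeds
#' `fold_threshold` (default 4).
#'
#' @param c_target Target-gene concentration, copies/uL.
#' @param c_reference Reference-gene concentration, copies/uL.
#' @param fold_threshold Amplification call threshold; default 4, strict.
#' @return A `cnv_result` with fields `c_target`, `c_reference`, `fold`,
#'   `amplified`.
#' @examples
#' cnv_fold(128, 4)   # fold 32, amplified
#' cnv_fold(4, 1)     # fold 4, NOT amplified (strict >)
#' @export
cnv_fold <- function(c_target, c_reference, fold_threshold = 4) {
  if (any(c(c_target, c_reference) < 0))
    ddctdna_error("concentrations must be non-negative", "ddctdna_validation_error")
  if (c_reference == 0)
    ddctdna_error("reference concentration is zero: fold ratio undefined",
                  "ddctdna_undefined_ratio")
  fold <- c_target / c_reference
  structure(list(c_target = c_target, c_reference = c_reference,
                 fold = fold, amplified = fold > fold_threshold,
                 fold_threshold = fold_threshold),
            class = "cnv_result")
}

#' @export
print.cnv_result <- function(x, ...) {
  cat(sprintf("copy-number fold: %.3g (target %.4g / reference %.4g copies/uL) -> %s\n",
              x$fold, x$c_target, x$c_reference,
              if (x$amplified) sprintf("AMPLIFIED (> %g-fold)", x$fold_threshold)
              else "not amplified"))
  invisible(x)
}
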