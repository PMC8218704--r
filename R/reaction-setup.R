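#' Reaction setup: volumes and constants of a ddPCR experiment
#'
#' Bundles every volume and physical constant needed to carry droplet counts
#' back to concentrations in the original biofluid. The back-calculation
#' chain is: copies/uL of PCR mix (Poisson inversion of droplet counts) ->
#' copies/mL of biofluid (via the reaction, eluate and sample volumes) ->
#' ng/mL of cell-free DNA (via the haploid genome mass).
#'
#' @param v_pcr Final PCR mix volume in uL.
#' @param v_elu DNA eluate volume in uL (volume the extraction was eluted in).
#' @param v_dna_pcr Volume of eluate loaded into the PCR reaction, in uL.
#'   Must not exceed `v_elu`.
#' @param v_sample Biofluid volume the DNA was extracted from, in mL.
#' @param droplet_volume Single droplet volume in nL. Default 0.85 nL, the
#'   conventional droplet volume of nanoliter droplet generators.
#' @param genome_mass Mass of one haploid human genome in ng. Default
#'   0.003 ng; configurable for users who prefer the 0.0033 convention.
#'
#' @return An object of class `reaction_setup` (a named list of the six
#'   validated constants).
#'
#' @examples
#' reaction_setup(v_pcr = 20, v_elu = 50, v_dna_pcr = 10, v_sample = 2)
#' @export
reaction_setup <- function(v_pcr = 20, v_elu = 50, v_dna_pcr = 10,
                           v_sample = 1, droplet_volume = 0.85,
                           genome_mass = 0.003) {
  vols <- c(v_pcr = v_pcr, v_elu = v_elu, v_dna_pcr = v_dna_pcr,
            v_sample = v_sample, droplet_volume = droplet_volume,
            genome_mass = genome_mass)
  if (!all(is.finite(vols)) || any(vols <= 0))
    ddctdna_error("all reaction volumes and constants must be finite and strictly positive",
                  "ddctdna_invalid_setup")
  if (v_dna_pcr > v_elu)
    ddctdna_error("v_dna_pcr cannot exceed v_elu (cannot load more eluate than exists)",
                  "ddctdna_invalid_setup")
  structure(as.list(vols), class = "reaction_setup")
}

#' @export
print.reaction_setup <- function(x, ...) {
  cat("ddPCR reaction setup\n")
  cat(sprintf("  PCR mix volume:       %g uL\n", x$v_pcr))
  cat(sprintf("  eluate volume:        %g uL (loaded: %g uL)\n", x$v_elu, x$v_dna_pcr))
  cat(sprintf("  biofluid volume:      %g mL\n", x$v_sample))
  cat(sprintf("  droplet volume:       %g nL\n", x$droplet_volume))
  cat(sprintf("  haploid genome mass:  %g ng\n", x$genome_mass))
  invisible(x)
}

is_reaction_setup <- function(x) inherits(x, "reaction_setup")
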