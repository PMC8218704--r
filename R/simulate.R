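# Droplet-level simulator of Poisson template partitioning.
#
# The generative model mirrors what a droplet generator does physically:
# a known DNA mass is converted to haploid genome copies (mass / 0.003 ng),
# split into mutant and wild-type allele copies by the true VAF, and the
# copies are scattered at random over ~15,000 droplets. Occupancy per
# droplet and channel is Poisson (independent-Poisson variant, the standard
# ddPCR model matching the inversion formula) or exactly multinomial
# (conservation variant). Fluorescence amplitudes are then drawn from
# Gaussian positive/negative clusters per channel, with optional "rain"
# (intermediate droplets) and optional per-droplet false positives.

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Design of a simulated ddPCR well
#'
#' Defaults emulate the study conditions of a validated liquid-biopsy ddPCR
#' workup: 5 ng DNA input (the anticipated low ctDNA amount), ~15,000
#' droplets of 0.85 nL, 0.003 ng per haploid genome, and cleanly separated
#' fluorescence clusters (no published amplitude statistics exist, so
#' cluster locations are a documented convention, not a measured fact).
#'
#' @param n_droplets Accepted droplets per well (default 15000).
#' @param droplet_volume Droplet volume, nL (default 0.85).
#' @param dna_input DNA mass loaded into the reaction, ng (default 5).
#' @param true_vaf True mutant allele fraction in `[0, 1]`.
#' @param genome_mass ng per haploid genome (default 0.003).
#' @param neg_mean,neg_sd Negative-cluster amplitude mean/SD (both channels).
#' @param pos_mean,pos_sd Positive-cluster amplitude mean/SD (both channels).
#' @param rain_fraction Fraction of droplets re-drawn uniformly between the
#'   cluster means ("rain"); default 0.
#' @param false_positive_rate Per-droplet probability that an unoccupied
#'   channel nevertheless fluoresces positive; default 0.
#' @param partitioning `"poisson"` (independent Poisson occupancy per
#'   channel; default) or `"multinomial"` (copies scattered exactly, total
#'   conserved).
#' @param seed Integer master seed.
#' @return A `simulation_design`.
#' @export
simulation_design <- function(n_droplets = 15000, droplet_volume = 0.85,
                              dna_input = 5, true_vaf = 0.01,
                              genome_mass = 0.003,
                              neg_mean = 1000, neg_sd = 150,
                              pos_mean = 8000, pos_sd = 300,
                              rain_fraction = 0, false_positive_rate = 0,
                              partitioning = c("poisson", "multinomial"),
                              seed = 1L) {
  partitioning <- match.arg(partitioning)
  if (n_droplets <= 0 || droplet_volume <= 0 || dna_input < 0 || genome_mass <= 0)
    ddctdna_error("n_droplets, droplet_volume, genome_mass must be positive; dna_input non-negative",
                  "ddctdna_validation_error")
  if (true_vaf < 0 || true_vaf > 1)
    ddctdna_error("true_vaf must lie in [0, 1]", "ddctdna_validation_error")
  if (neg_sd <= 0 || pos_sd <= 0)
    ddctdna_error("cluster SDs must be positive", "ddctdna_validation_error")
  if (rain_fraction < 0 || rain_fraction > 1 ||
      false_positive_rate < 0 || false_positive_rate > 1)
    ddctdna_error("rain_fraction and false_positive_rate must lie in [0, 1]",
                  "ddctdna_validation_error")
  structure(list(n_droplets = as.integer(n_droplets),
                 droplet_volume = droplet_volume, dna_input = dna_input,
                 true_vaf = true_vaf, genome_mass = genome_mass,
                 neg_mean = neg_mean, neg_sd = neg_sd,
                 pos_mean = pos_mean, pos_sd = pos_sd,
                 rain_fraction = rain_fraction,
                 false_positive_rate = false_positive_rate,
                 partitioning = partitioning, seed = as.integer(seed)),
            class = "simulation_design")
}

# template copies implied by a design: total = floor(mass/genome mass),
# mutant = round(total * VAF), wild-type = remainder
design_copies <- function(design) {
  total <- floor(design$dna_input / design$genome_mass)
  n_mut <- round(total * design$true_vaf)
  c(mut = n_mut, wt = total - n_mut, total = total)
}

# scatter `copies` template molecules over n droplets; returns per-droplet
# occupancy. poisson: iid Poisson(copies/n) (total conserved in expectation);
# multinomial: exact scatter (total conserved exactly).
scatter_copies <- function(copies, n, partitioning) {
  if (partitioning == "poisson") return(rpois(n, copies / n))
  occ <- integer(n)
  if (copies > 0) {
    hit <- tabulate(sample.int(n, size = copies, replace = TRUE), nbins = n)
    occ <- occ + hit
  }
  occ
}

#' Simulate one ddPCR well
#'
#' @param design A [simulation_design].
#' @return A `simulated_well`: list with `table` (an [amplitude_table]),
#'   `labels` (ground-truth per-droplet class from template occupancy,
#'   before any false-positive injection), `occupancy` (two-column matrix
#'   of mutant/wild-type copies per droplet), and `truth` (designed copy
#'   numbers and the partitioning variant used).
#' @export
simulate_well <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  cp <- design_copies(design)
  n <- design$n_droplets
  with_seed(design$seed, {
    occ_mut <- scatter_copies(cp[["mut"]], n, design$partitioning)
    occ_wt <- scatter_copies(cp[["wt"]], n, design$partitioning)

    pos1 <- occ_mut >= 1
    pos2 <- occ_wt >= 1
    labels <- rep("empty", n)
    labels[pos1 & !pos2] <- "mutant"
    labels[!pos1 & pos2] <- "wild_type"
    labels[pos1 & pos2] <- "double"

    draw <- function(pos) ifelse(pos,
      rnorm(n, design$pos_mean, design$pos_sd),
      rnorm(n, design$neg_mean, design$neg_sd))
    # false positives flip an unoccupied channel's amplitude to the
    # positive cluster; ground-truth labels are left untouched
    fp1 <- !pos1 & runif(n) < design$false_positive_rate
    fp2 <- !pos2 & runif(n) < design$false_positive_rate
    ch1 <- draw(pos1 | fp1)
    ch2 <- draw(pos2 | fp2)
    rain <- runif(n) < design$rain_fraction
    if (any(rain)) {
      ch1[rain] <- runif(sum(rain), design$neg_mean, design$pos_mean)
      ch2[rain] <- runif(sum(rain), design$neg_mean, design$pos_mean)
    }
    tab <- amplitude_table(
      data.frame(ch1 = pmax(ch1, 0), ch2 = pmax(ch2, 0)),
      well_id = sprintf("sim-%d", design$seed))
    structure(list(table = tab, labels = labels,
                   occupancy = cbind(mut = occ_mut, wt = occ_wt),
                   truth = list(mut_copies = unname(cp[["mut"]]),
                                wt_copies = unname(cp[["wt"]]),
                                total_copies = unname(cp[["total"]]),
                                partitioning = design$partitioning)),
              class = "simulated_well")
  })
}

#' Ground-truth well counts of a simulated well
#'
#' Tallies the occupancy-derived labels (what an ideal classifier would
#' report) into a [well_counts].
#'
#' @param well A `simulated_well`.
#' @return A [well_counts].
#' @export
true_well_counts <- function(well) {
  stopifnot(inherits(well, "simulated_well"))
  pos1 <- well$occupancy[, "mut"] >= 1
  pos2 <- well$occupancy[, "wt"] >= 1
  well_counts(n_total = length(pos1), n_mut = sum(pos1),
              n_wt = sum(pos2), n_double = sum(pos1 & pos2))
}

#' Simulate a serial-dilution limit-of-detection experiment
#'
#' Emulates the standard LoD design: the mutant DNA is serially diluted
#' into a CONSTANT concentration of wild-type DNA (mutant copies scaled by
#' 1/factor, wild-type copies held at the neat design's value) and each
#' point is run in replicate wells. Replicate wells receive distinct child
#' seeds derived from the design's master seed, so the series is fully
#' reproducible yet replicates differ.
#'
#' @param neat_design [simulation_design] of the undiluted mutant sample.
#' @param factors Dilution factors, ascending; default
#'   `c(10, 100, 1000, 10000)`.
#' @param replicates Wells per dilution point; default 2 (duplicate).
#' @return List of [dilution_point]s (mutant/wild-type droplet counts per
#'   replicate, from ground-truth occupancy), with the simulated wells in
#'   attribute `"wells"`.
#' @export
simulate_dilution_series <- function(neat_design,
                                     factors = c(10, 100, 1000, 10000),
                                     replicates = 2) {
  stopifnot(inherits(neat_design, "simulation_design"))
  if (any(factors < 1) || is.unsorted(factors))
    ddctdna_error("factors must be >= 1 and ascending", "ddctdna_validation_error")
  cp <- design_copies(neat_design)
  wells <- list()
  counter <- 0L
  points <- lapply(factors, function(f) {
    reps_mut <- integer(replicates)
    reps_wt <- integer(replicates)
    for (r in seq_len(replicates)) {
      counter <<- counter + 1L
      seed_r <- derive_seed(neat_design$seed, counter)
      n <- neat_design$n_droplets
      w <- with_seed(seed_r, {
        occ_mut <- if (neat_design$partitioning == "poisson")
          rpois(n, (cp[["mut"]] / f) / n)
        else scatter_copies(round(cp[["mut"]] / f), n, "multinomial")
        occ_wt <- scatter_copies(cp[["wt"]], n, neat_design$partitioning)
        list(mut = sum(occ_mut >= 1), wt = sum(occ_wt >= 1))
      })
      reps_mut[r] <- w$mut
      reps_wt[r] <- w$wt
      wells[[length(wells) + 1L]] <<- list(factor = f, replicate = r,
                                           seed = seed_r, counts = w)
    }
    dilution_point(f, reps_mut, reps_wt)
  })
  attr(points, "wells") <- wells
  points
}

# per-biofluid cohort defaults emulating a pediatric high-grade glioma /
# DIPG liquid-biopsy feasibility cohort: detection is much likelier in CSF
# than in blood compartments, and detected CSF samples carry far higher
# VAFs (median ~15%) than plasma (~0.8%) or serum (~0.2%)
cohort_defaults <- function() {
  list(
    n_samples = c(plasma = 27, CSF = 9, serum = 6, cyst = 1),
    positivity = c(plasma = 0.26, CSF = 0.67, serum = 0.33, cyst = 1),
    vaf_median = c(plasma = 0.0078, CSF = 0.1533, serum = 0.0022, cyst = 0.4268),
    vaf_sdlog = c(plasma = 1, CSF = 1, serum = 1, cyst = 0.5)
  )
}

#' Simulate a liquid-biopsy cohort
#'
#' Draws per-sample positivity (Bernoulli per biofluid), a true VAF for
#' positive samples (log-normal around the biofluid's median, zero for
#' designed-negative samples), and droplet counts from the Poisson
#' occupancy model. Designed-positive samples are conditioned on actually
#' showing at least two mutant droplets (redrawn otherwise), so the
#' designed positivity parameter is the exact detection rate in
#' expectation — this is what "zero-inflated" means here.
#'
#' @param n_samples Named integer vector of samples per biofluid; names
#'   from `{plasma, serum, CSF, cyst}`.
#' @param positivity Named vector of per-fluid positivity probabilities.
#' @param vaf_median Named vector of per-fluid median true VAF for positive
#'   samples.
#' @param vaf_sdlog Named vector of log-scale SDs of the VAF distribution.
#' @param dna_input DNA input per reaction, ng (default 5).
#' @param n_droplets Accepted droplets per well (default 15000).
#' @param genome_mass ng per haploid genome (default 0.003).
#' @param seed Integer master seed.
#' @return A `simulated_cohort`: list with `samples` (a [sample_sheet]),
#'   `counts` (data.frame of n_total/n_mut/n_wt per sample) and `truth`
#'   (designed positivity and true VAF per sample).
#' @export
simulate_cohort <- function(n_samples = cohort_defaults()$n_samples,
                            positivity = cohort_defaults()$positivity,
                            vaf_median = cohort_defaults()$vaf_median,
                            vaf_sdlog = cohort_defaults()$vaf_sdlog,
                            dna_input = 5, n_droplets = 15000,
                            genome_mass = 0.003, seed = 1L) {
  fluids <- names(n_samples)
  if (is.null(fluids) || !all(fluids %in% BIOFLUIDS))
    ddctdna_error("n_samples must be named with biofluids from: plasma, serum, CSF, cyst",
                  "ddctdna_validation_error")
  if (any(n_samples <= 0))
    ddctdna_error("sample counts must be positive", "ddctdna_validation_error")
  total_copies <- floor(dna_input / genome_mass)
  with_seed(seed, {
    rows <- list()
    for (fluid in fluids) {
      for (i in seq_len(n_samples[[fluid]])) {
        designed_pos <- runif(1) < positivity[[fluid]]
        for (try in seq_len(1000)) {
          if (designed_pos) {
            vaf <- min(rlnorm(1, log(vaf_median[[fluid]]), vaf_sdlog[[fluid]]), 1)
          } else vaf <- 0
          mut_copies <- round(total_copies * vaf)
          wt_copies <- total_copies - mut_copies
          n_mut <- rbinom(1, n_droplets, 1 - exp(-mut_copies / n_droplets))
          n_wt <- rbinom(1, n_droplets, 1 - exp(-wt_copies / n_droplets))
          # condition designed positives on reaching the detection rule
          if (!designed_pos || n_mut >= 2) break
        }
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = sprintf("SIM-%s-%03d", fluid, i),
          assay_id = "SIM_ASSAY", sample_type = fluid,
          biofluid_volume = 1, time_point = "1",
          n_total = n_droplets, n_mut = n_mut, n_wt = n_wt,
          designed_positive = designed_pos, true_vaf = vaf)
      }
    }
    all <- do.call(rbind, rows)
    structure(list(
      samples = sample_sheet(all[, c("patient_id", "assay_id", "sample_type",
                                     "biofluid_volume", "time_point")]),
      counts = all[, c("patient_id", "n_total", "n_mut", "n_wt")],
      truth = all[, c("patient_id", "designed_positive", "true_vaf")]),
      class = "simulated_cohort")
  })
}
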