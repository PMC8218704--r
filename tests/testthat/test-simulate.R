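test_that("a null allele yields zero mutant templates at every seed", {
  for (seed in 1:5) {
    w <- simulate_well(simulation_design(true_vaf = 0, seed = seed))
    expect_equal(sum(w$occupancy[, "mut"]), 0)
    expect_false(any(w$labels %in% c("mutant", "double")))
  }
})

test_that("positive-droplet counts match the binomial occupancy oracle", {
  # wild-type occupancy 0.1 per droplet: 4.5 ng at 0.003 ng/copy = 1500
  # copies over 15000 droplets; expect 15000 * (1 - e^-0.1) ~ 1427.6
  d <- simulation_design(dna_input = 4.5, true_vaf = 0, seed = 19)
  w <- simulate_well(d)
  p <- 1 - exp(-0.1)
  expect_lt(abs(sum(w$occupancy[, "wt"] >= 1) - 15000 * p),
            3 * sqrt(15000 * p * (1 - p)))

  # dilute mutant channel: 5 ng, VAF 0.01 -> 17 mutant copies, and the
  # expected number of mutant-positive droplets is ~equal to the copies
  counts <- vapply(1:30, function(s) {
    w <- simulate_well(simulation_design(true_vaf = 0.01, seed = s))
    sum(w$occupancy[, "mut"] >= 1)
  }, numeric(1))
  mut_copies <- round(floor(5 / 0.003) * 0.01)
  expect_equal(mut_copies, 17)
  expect_lt(abs(mean(counts) - 15000 * (1 - exp(-mut_copies / 15000))),
            3 * sqrt(mut_copies / 30))
})

test_that("multinomial partitioning conserves template copies exactly", {
  d <- simulation_design(true_vaf = 0.05, partitioning = "multinomial", seed = 3)
  w <- simulate_well(d)
  expect_equal(sum(w$occupancy[, "mut"]), w$truth$mut_copies)
  expect_equal(sum(w$occupancy[, "wt"]), w$truth$wt_copies)
  expect_equal(w$truth$mut_copies + w$truth$wt_copies, floor(5 / 0.003))
  expect_equal(w$truth$partitioning, "multinomial")
})

test_that("simulation is reproducible from the seed and leaves the RNG alone", {
  d <- simulation_design(true_vaf = 0.02, seed = 77)
  w1 <- simulate_well(d)
  set.seed(123)  # simulator must not be perturbed by ambient RNG state
  w2 <- simulate_well(d)
  expect_identical(w1, w2)
  s1 <- simulate_cohort(seed = 5)
  s2 <- simulate_cohort(seed = 5)
  expect_identical(s1, s2)
  expect_false(identical(s1$counts, simulate_cohort(seed = 6)$counts))
})

test_that("dilution series scale the mutant only and derive distinct seeds", {
  d <- simulation_design(true_vaf = 0.793, seed = 21)
  ser <- simulate_dilution_series(d, factors = c(1, 10, 100, 1000, 10000))
  expect_length(ser, 5)
  # wild-type background constant across factors (constant concentration)
  wt_means <- vapply(ser, function(pt) mean(pt$wt), numeric(1))
  wt_copies <- floor(5 / 0.003) - round(floor(5 / 0.003) * 0.793)
  p_wt <- 1 - exp(-wt_copies / 15000)
  for (m in wt_means)
    expect_lt(abs(m - 15000 * p_wt), 4 * sqrt(15000 * p_wt * (1 - p_wt)))
  # mutant droplets fall ~10-fold per step
  mut_pooled <- vapply(ser, function(pt) sum(pt$mutant), numeric(1))
  expect_true(all(diff(mut_pooled) <= 0))
  expect_true(all(diff(mut_pooled[1:4]) < 0))
  # factor 1 reproduces the neat design's expectation
  mut_copies <- round(floor(5 / 0.003) * 0.793)
  p_mut <- 1 - exp(-mut_copies / 15000)
  expect_lt(abs(mean(ser[[1]]$mutant) - 15000 * p_mut),
            4 * sqrt(15000 * p_mut * (1 - p_mut)))
  # deepest point: ~0.13 expected copies -> usually zero droplets
  deep <- vapply(1:20, function(s) {
    sum(simulate_dilution_series(simulation_design(true_vaf = 0.793, seed = s),
                                 factors = c(10000))[[1]]$mutant)
  }, numeric(1))
  expect_gt(mean(deep == 0), 0.5)
  expect_lt(mean(deep), 1.5)
  # replicate wells differ (distinct child seeds) but reruns reproduce
  ser2 <- simulate_dilution_series(d, factors = c(1, 10, 100, 1000, 10000))
  expect_identical(ser[[1]]$mutant + 0L, ser2[[1]]$mutant)
  expect_false(all(ser[[2]]$wt[1] == ser[[2]]$wt[2]) &&
               all(ser[[1]]$wt[1] == ser[[1]]$wt[2]))
})

test_that("simulated series yield the expected LoD whenever the ladder detects", {
  # conditional arithmetic oracle: whenever 1:100 is detectable and 1:1000
  # is not, the LoD equals neat/100; in every case the LoD equals the
  # neat VAF over the largest detectable factor, recomputed directly
  hits <- 0
  for (seed in 1:15) {
    d <- simulation_design(true_vaf = 0.793, seed = seed)
    ser <- simulate_dilution_series(d)
    pooled <- vapply(ser, function(pt) sum(pt$mutant), numeric(1))
    factors <- vapply(ser, `[[`, numeric(1), "dilution_factor")
    if (!any(pooled >= 2)) next
    r <- compute_lod(0.793, ser)
    expect_equal(r$lod, 0.793 / max(factors[pooled >= 2]))
    if (pooled[factors == 100] >= 2 && pooled[factors == 1000] < 2) {
      hits <- hits + 1
      expect_equal(r$lod, 0.00793)
    }
  }
  expect_gt(hits, 0)
})

test_that("count-ratio AF spread shrinks as droplet occupancy grows", {
  af_at <- function(dna, seeds) vapply(seeds, function(s) {
    wc <- true_well_counts(simulate_well(
      simulation_design(dna_input = dna, true_vaf = 0.05, seed = s)))
    allele_fraction(wc$n_mut, wc$n_wt)
  }, numeric(1))
  expect_gt(sd(af_at(1, 1:60)), sd(af_at(25, 61:120)))
})

test_that("cohort simulation reproduces the designed positivity structure", {
  # positivity zero everywhere: nothing reaches two mutant droplets
  s0 <- simulate_cohort(positivity = c(plasma = 0, CSF = 0, serum = 0, cyst = 0),
                        seed = 2)
  expect_true(all(s0$counts$n_mut == 0))
  expect_false(any(call_positivity(s0$counts$n_mut)))

  # recovered positivity matches the parameters within 3 SE (binomial)
  reps <- 300
  pos_csf <- pos_pla <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_cohort(seed = r)
    joined <- merge(sim$samples, sim$counts, by = "patient_id")
    pos <- call_positivity(joined$n_mut)
    pos_csf[r] <- mean(pos[joined$sample_type == "CSF"])
    pos_pla[r] <- mean(pos[joined$sample_type == "plasma"])
  }
  se_csf <- sqrt(0.67 * 0.33 / (9 * reps))
  se_pla <- sqrt(0.26 * 0.74 / (27 * reps))
  expect_lt(abs(mean(pos_csf) - 0.67), 3 * se_csf)
  expect_lt(abs(mean(pos_pla) - 0.26), 3 * se_pla)

  # designed positivity is recovered sample-by-sample (conditioning)
  sim <- simulate_cohort(seed = 9)
  expect_equal(call_positivity(sim$counts$n_mut), sim$truth$designed_positive)
})
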