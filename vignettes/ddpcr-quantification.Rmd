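---
title: "Droplet digital PCR quantification of circulating tumor DNA: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Droplet digital PCR quantification of circulating tumor DNA: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddctdna)
```

## The measurement model

Droplet digital PCR turns quantification into counting. A PCR reaction of
volume $V_{PCR}$ (default 20 µL) is emulsified into roughly 15,000
droplets of volume $V_d$ (default 0.85 nL, the conventional droplet
volume of nanoliter generators; the instrument reports only "accepted"
droplets, which is the count the package works with). Template molecules
are scattered at random, so the number of copies in a droplet is Poisson
with mean occupancy $\lambda = c \, V_d$, where $c$ is the concentration
of the mix. After endpoint PCR each droplet fluoresces on the mutant
channel (FAM) if it carried at least one mutant template, and on the
wild-type channel (VIC/HEX) if it carried wild type; droplets carrying
both are double positives and count toward *both* channel totals.

From the positive fraction $\hat p = n_{pos}/n_{total}$ on a channel,

$$\hat\lambda = -\ln(1-\hat p), \qquad \hat c = \hat\lambda / V_d ,$$

implemented in `poisson_concentration()`. The inversion is undefined at
saturation ($n_{pos} = n_{total}$), which is reported as an error rather
than a clipped value: a saturated well carries no upper-bound
information.

### Allele fraction: two estimators

`allele_fraction()` offers two modes.

* `count_ratio` (default): $n_{mut}/(n_{mut}+n_{wt})$. This is the
  convention of published ddPCR liquid-biopsy tables — every VAF in the
  bundled detected-sample table is exactly this quotient — and it is the
  default for that reason.
* `poisson`: $\hat\lambda_{mut}/(\hat\lambda_{mut}+\hat\lambda_{wt})$,
  which estimates the *copy* fraction.

The two agree to about $10^{-3}$ absolute below ~5 % channel occupancy.
Above that, multiply occupied droplets make the positive-droplet count
undercount the majority channel, so the count ratio overstates the minor
allele: at a typical 5 ng input (~1,666 haploid copies over 15,000
droplets, wild-type occupancy $\lambda \approx 0.11$) the count-ratio
VAF sits roughly $\lambda_{wt}/2 \approx 5\%$ *relative* above the copy
fraction. This is a property of the estimand, not a bug; the test suite
checks each estimator against its own expectation (the Poisson mode
against the true copy fraction, the count ratio against its closed-form
positive-fraction ratio) rather than pretending the count ratio is an
unbiased copy-fraction estimator. The same effect explains why published
per-channel ng/mL values (derived from Poisson-corrected concentrations)
imply a slightly lower mass-ratio VAF than the printed count-ratio VAF,
diverging by ~2 percentage points for the one high-occupancy cystic-fluid
sample in the example cohort.

### Back to the biofluid

With $V_{ELU}$ the elution volume of the cfDNA extraction, $V_{DNA-PCR}$
the eluate volume loaded into the reaction, and $V_{SAMPLE}$ the
biofluid volume in mL,

$$C_{ori} = \frac{V_{PCR} \cdot c \cdot V_{ELU}}{V_{DNA-PCR} \cdot V_{SAMPLE}}
\quad \text{(copies/mL biofluid)},$$

which is plain copy bookkeeping: copies in the reaction, scaled up to
the full eluate, divided by the biofluid volume. The cfDNA mass
concentration multiplies total allele copies by the mass of one haploid
genome, $C_{cfDNA} \approx 0.003 \times (C_{MUT,ori} + C_{WT,ori})$
ng/mL. The 0.003 ng constant is the package default (`reaction_setup()`),
configurable for the 0.0033 ng convention some laboratories use.

### Positivity and copy number

A sample is called positive at **two or more mutant droplets**
(`call_positivity()`, threshold configurable). One droplet is never
enough: singleton events occur in otherwise negative samples at rates
compatible with rare false positives, and the bundled example cohort
contains seven such singleton samples, all called negative. MYCN-style
amplification calls (`cnv_fold()`) use the raw target/reference
concentration ratio with a **strict** > 4-fold rule; no ploidy factor is
applied, since the assay compares two loci in the same reaction.

## Limit of detection

`compute_lod()` implements the operational serial-dilution rule: mutant
DNA is diluted 1:10 … 1:10,000 into a *constant* wild-type background
and run in duplicate; the LoD is the neat sample's fractional abundance
divided by the deepest dilution factor still detectable (≥ 2 mutant
droplets). Duplicates are pooled (summed) before the rule by default —
this uses both wells' droplets, which is the natural reading of a
detection threshold on counts — with `replicate_rule = "any"` available
for the stricter per-well alternative, since the choice is not dictated
by the definition itself.

A subtlety worth recording: with 10-fold dilution steps, a pooled ≥ 2
rule and Poisson counting, no input mass makes the ladder's stopping
point deterministic. If the expected pooled mutant droplets at some
level are $e$, the probability of detecting that level and *not* the
next is $P(\ge 2 \mid e)\,(1 - P(\ge 2 \mid e/10))$, which never exceeds
~0.875 over $e$. The simulator tests therefore check the conditional
property — whenever the ladder detects 1:100 and not 1:1000, the LoD is
neat/100 — and the exact arithmetic on observed detectability patterns,
not an unconditional reproduction probability.

## Droplet classification

`classify_droplets()` uses per-channel thresholds with strict
inequality; ties classify negative (one rule, applied everywhere).
Thresholds can be fixed or derived from control wells by the k-sigma
rule (`estimate_thresholds()`): cutoff = mean + k·SD of the
negative-control amplitudes, default k = 5, with a separation warning if
a cutoff reaches the positive-control cluster mean. A deterministic rule
was chosen over 2-D clustering because assays are validated against
control wells and a threshold rule is exactly testable; model-based
clustering and per-plate drift correction are out of scope.

## The simulator

`simulate_well()` draws what the physics does: total haploid copies =
⌊mass / 0.003 ng⌋ (1,666 at the 5 ng default), mutant copies = round(total
× VAF), per-droplet occupancy independent Poisson per channel (the model
the inversion formula assumes) or exact multinomial scattering (for
conservation tests; the variant used is recorded on the output).
Amplitudes come from Gaussian clusters — negative mean 1000 SD 150,
positive mean 8000 SD 300 on both channels, a > 20 SD separation chosen
for clean validation since no published amplitude statistics exist —
with optional uniform "rain" between the cluster means and an optional
per-droplet false-positive rate (default 0: wild-type template controls
in validated assays show no mutant droplets). Ground-truth labels always
reflect template occupancy, *before* false-positive injection.

Seed discipline: every well is reproducible from its design seed;
dilution series and cohorts derive per-well child seeds from the master
seed by a linear-congruential counter scheme, so replicates differ while
whole runs reproduce byte-identically.

`simulate_cohort()` emulates the biofluid structure of a pediatric
high-grade glioma feasibility cohort: per-fluid sample counts (27
plasma, 9 CSF, 6 serum, 1 cyst), per-fluid positivity probabilities
(0.26, 0.67, 0.33, 1) and log-normal VAF distributions for positive
samples centred on the observed per-fluid medians (plasma 0.78 %, CSF
15.33 %, serum 0.22 %, cyst 42.7 %), with 5 ng input. Designed-positive
samples are conditioned (redrawn) on actually reaching two mutant
droplets, so the positivity parameter is the exact expected detection
rate — that is what makes the zero-inflation parameter recoverable.

What the simulator does **not** model: PCR chemistry and efficiency,
droplet-volume variability, fragment-size effects on probe binding, and
cross-contamination. Passing tests therefore demonstrate correctness of
the counting statistics and the analysis chain, not robustness to every
artifact of real instruments.

## Fusion-candidate filtering

`filter_candidates()` applies six rejection rules to capture-panel
structural-variant candidates: read support below 3 on either gene
("more than 2 reads", read strictly; the ≥ 2 alternative is a plausible
reading, so the threshold is a parameter), both breakpoints off-panel
(one baited end suffices to keep, as in capture designs where only one
partner is targeted), breakpoints within 10 bp of a blocklisted
recurrent false-positive position, blocklisted gene pairs (unordered),
intragenic events, and junction homology strictly above 10 bp.
Blocklists are user-supplied resources; empty blocklists are valid.
Every rejection names its first failing rule and all failing rules, and
filtering is idempotent and order-independent.

Coordinates: capture intervals are BED (0-based, half-open) on disk and
stay half-open internally; candidate breakpoints are 1-based. The
membership contract is that a 1-based position equal to a BED end
coordinate is *outside* the interval, with the conversion centralized in
`load_capture_bed()` / `capture_contains()`.

## Numerical and degenerate-input choices

* Saturated wells and zero-reference CNV ratios are errors, not values.
* Absent inputs (no total droplet count, no reaction setup) propagate as
  `NA` fields in `run_sample()` results — never as zeros.
* Serialized VAFs (percent) and ng/mL values are written with 3
  decimals, the precision of published tables; exact values are always
  retained in memory.
* Cohort positivity percentages are displayed round-half-up to integers
  (26, 67, 33 for the example cohort) with exact fractions alongside.
* Cystic fluid is a first-class biofluid category, not folded into CSF.

## Problem sizes in the test suite

The Monte-Carlo checks use 1,000 partitioning replicates at 15,000
droplets for the Poisson-inversion oracle, 200 simulated wells per VAF
level for estimator consistency, and 100 seeds for classification
fidelity — sizes at which the binomial standard errors are an order of
magnitude below the effects being checked.

## Known limitations

No confidence intervals on λ (a natural extension via the binomial
variance of $\hat p$); no probit-regression LoD (only the operational
dilution rule); no multi-well merging beyond replicate pooling in the
LoD module; group-comparison statistics (ANOVA and friends) are
deliberately excluded — the cohort summary exposes the per-group values
needed to run any such test externally.
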