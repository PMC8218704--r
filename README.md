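# ddctdna

Quantification of circulating tumor DNA (ctDNA) from droplet digital PCR
(ddPCR) assays of liquid biopsies — plasma, serum, cerebrospinal fluid
(CSF) and cystic fluid — with a focus on the low-input setting of
pediatric high-grade glioma and diffuse midline glioma, where a few
nanograms of cell-free DNA (cfDNA) must be interrogated for hotspot
driver mutations (H3F3A K27M/G34R, IDH1 R132H, BRAF V600E, ACVR1,
TP53, PIK3CA), MYCN amplification, and gene fusions.

## What it computes

A ddPCR reaction partitions the sample into ~15,000 nanoliter droplets
read on two fluorescence channels (FAM for the mutant probe, VIC/HEX for
wild type). From the classified droplet tallies the package computes:

- **Absolute concentration** by Poisson inversion: with positive-droplet
  fraction *p*, the per-droplet occupancy is λ = −ln(1 − *p*) and the
  concentration of the PCR mix is C = λ / V_droplet (copies/µL).
- **Variant allele fraction**: AF = C_MUT / (C_MUT + C_WT), either as the
  raw droplet-count quotient n_mut / (n_mut + n_wt) (the convention of
  published ddPCR tables) or Poisson-corrected from channel occupancies.
- **Back-calculation to the biofluid**:
  C_ori = (V_PCR × C × V_ELU) / (V_DNA-PCR × V_SAMPLE) in copies/mL, and
  cfDNA mass concentration C_cfDNA ≈ 0.003 × (C_MUT_ori + C_WT_ori)
  ng/mL, using 0.003 ng per haploid genome.
- **Positivity**: a sample is positive with ≥ 2 mutant droplets.
- **Limit of detection** from a serial-dilution experiment: neat
  fractional abundance divided by the deepest dilution still detectable.
- **Copy-number amplification**: target/reference concentration ratio,
  called amplified when strictly > 4-fold.
- **Fusion-candidate filtering** for capture-panel structural-variant
  calls (read support, capture membership, breakpoint/gene-pair
  blocklists, intragenic and high-homology removal).
- **Cohort summaries**: per-biofluid positivity and longitudinal cfDNA
  concentration series.

A droplet-level simulator (Poisson or exact-multinomial template
partitioning, Gaussian fluorescence clusters, optional rain and false
positives) generates fully reproducible synthetic wells, dilution series
and cohorts for validation.

## Worked example

```r
library(ddctdna)

# a plasma sample: 10 mutant and 398 wild-type droplets from 2.7 mL
res <- run_sample(10, 398, n_total = 15000,
                  setup = reaction_setup(v_pcr = 20, v_elu = 50,
                                         v_dna_pcr = 10, v_sample = 2.7),
                  sample = list(patient_id = "013-T", sample_type = "plasma",
                                biofluid_volume = 2.7))
res
#> ddPCR quantification [013-T]
#>   VAF: 2.451% (count_ratio; 10 mutant / 398 wild-type droplets)
#>   cfDNA: 3.602 ng/mL (mutant 0.087, wild-type 3.515)
#>   call: POSITIVE (>= 2 mutant droplets)
```

The VAF is the droplet-count quotient 10/408 = 2.451 %; the cfDNA
concentrations convert the Poisson-inverted copies/µL back through the
reaction volumes to ng per mL of plasma. The bundled 43-sample example
cohort summarizes as:

```r
coh <- example_cohort()
coh$positive <- call_positivity(coh$mutant_droplets)
summarize_cohort(coh)
#> cohort positivity by biofluid (>= 2 mutant droplets):
#>   plasma  7/27 (26%)
#>   serum   2/6 (33%)
#>   CSF     6/9 (67%)
#>   cyst    1/1 (100%)
#>   total   16/43 (37%)
```

An assay's limit of detection from a 1:10–1:10,000 dilution ladder:

```r
series <- list(dilution_point(10, c(132, 132)), dilution_point(100, c(13, 13)),
               dilution_point(1000, c(1, 0)), dilution_point(10000, c(0, 0)))
compute_lod(neat_af = 0.793, series)
#> limit of detection: 0.793% (neat VAF 79.3% / deepest detectable
#> dilution 1:100; >=2 mutant droplets, pooled replicates)
```

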