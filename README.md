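# spliceratio

Quantitative analysis of how the ratio of mutant to wild-type
splicing-factor gene products controls 3' splice-site choice.

Recurrent point mutations in U2AF1 (canonically S34F in the zinc
knuckle) change which 3' splice sites the U2AF complex prefers —
largely through the nucleotide at the −3 position, immediately
upstream of the invariant intronic AG — and the strength of the
resulting splicing program tracks the mutant:wild-type ratio ρ rather
than the absolute level of either product. `spliceratio` is for
computational biologists who want that analysis chain as tested,
reusable components:

- **PSI quantification** (`compute_psi`, `psi_matrix`): percent
  spliced in from junction read counts, Ψ = inc/(inc+exc), with an
  informative-read floor (default 20) below which Ψ is undefined.
- **Signature calling** (`delta_psi_vs_reference`, `build_logo`,
  `classify_signature`): ΔΨ of each mutant sample against the
  reference-cohort median with an inclusive ±0.10 threshold; 3'
  splice-site consensus logos with per-position information content
  IC = 2 + Σ f·log₂f bits; a sample is "typical S34F" only when A > T
  at −3 of promoted-event acceptors *and* T > C at −3 of
  repressed-event acceptors, otherwise "quasi wild-type".
- **Allelic ratio** (`ratio_from_reads`, `ratio_from_qpcr`,
  `correlate_ratio_psi`): ρ = alt/ref from variant-spanning reads or
  from allele-sensitive qPCR with linear unmixing of probe
  cross-reactivity; Pearson correlation of ρ with event-level Ψ.
- **Binding affinity** (`fit_titration`, `fold_change`,
  `predict_direction`, `concordance`): two-state ligand-depletion
  isotherm fits to fluorescence anisotropy titrations,
  FB = ((P+R+K_D) − √((P+R+K_D)² − 4PR))/2R; Welch t-tests on log K_A
  fold changes; and a proximal/distal competition rule that predicts
  whether the mutant increases or decreases proximal-site use.
- **Synthetic data** (`simulate_events`, `simulate_cohort`,
  `simulate_titration`): seeded cohorts built on the occupancy model
  Ψ(ρ) = K(prox)/(K(prox)+K(dist)) with mixture affinities
  K = f·K_mut + (1−f)·K_wt, f = ρ/(1+ρ), with binomial read sampling
  and Gaussian anisotropy noise, plus full ground truth.
- **Pipeline** (`run_pipeline`): simulate → psi → signature → ratio →
  correlate → binding → predict from one YAML/R configuration, with a
  deterministic JSON run manifest.

## Worked example

The occupancy model for an event whose proximal 3' splice site (−3T)
loses mutant affinity — inclusion falls as the mutant fraction rises:

```r
library(spliceratio)
ev <- sim_event("STRAP_like", "T", ka_wt_prox = 1.5, ka_wt_dist = 1,
                ka_mut_prox = 0.5, ka_mut_dist = 1)
round(occupancy_psi(ev, c(0, 0.5, 1, 2)), 3)
#> [1] 0.600 0.538 0.500 0.455
```

A small end-to-end run — 30 wild-type plus 4 mutant samples at ratios
0.05–1.5 over 500 events:

```r
cfg <- default_config(seed = 42, out_dir = "demo_run", n_events = 500,
                      n_wt_samples = 30, n_mut_samples = 4,
                      ratio_per_mut_sample = c(0.05, 0.3, 0.8, 1.5),
                      n_binding_events = 2)
res <- run_pipeline(cfg)
res$state$signature_calls
#>   sample_id        class      score n_promoted n_repressed
#> 1   MUT_001     quasi_WT -0.1500000         20          13
#> 2   MUT_002     quasi_WT -0.1576027         53          17
#> 3   MUT_003 typical_S34F  0.6390476         84          25
#> 4   MUT_004 typical_S34F  0.7948718         91          39
```

The two low-ratio samples (ρ = 0.05, 0.3) show background-like −3
composition and are classified quasi wild-type; the high-ratio samples
(ρ = 0.8, 1.5) show the typical mutant pattern (positive score: A > T
before promoted exons and T > C before repressed exons). The binding
stage then titrates the simulated site pairs, fits affinities, and
checks the competition rule against the observed ΔΨ directions:

```r
res$state$concordance$table
#>   event_id predicted  observed concordant
#> 1   ev0007 decreased decreased       TRUE
#> 2   ev0009 increased increased       TRUE
```

Applying the same rule to the bundled direction-level encoding of the
seven experimentally titrated splice-site pairs reproduces the
published concordance:

```r
conc <- concordance(predict_from_table(tested_3ss_events()))
sprintf("%d/%d", conc$concordant, conc$total)
#> [1] "6/7"
```

A thin command-line wrapper is installed at
`system.file("scripts", "splice-ratio.R", package = "spliceratio")`:

```sh
Rscript splice-ratio.R run --seed 7 --out-dir results/
```

See `vignettes/ratio-dependent-splicing.Rmd` for the models, their
assumptions, and every numerical choice.

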