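---
title: "Ratio-dependent 3' splice-site choice: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratio-dependent 3' splice-site choice: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceratio)
```

## The problem

Recurrent point mutations in the splicing factor U2AF1 — most
prominently S34F in its zinc knuckle — change which 3' splice sites the
U2AF complex prefers, shifting the inclusion of hundreds of cassette
exons. Tumours carrying such mutations always retain the wild-type
allele, and the magnitude of the mutant-associated splicing program
tracks the *ratio* of mutant to wild-type gene products rather than the
absolute level of either. `spliceratio` packages the quantitative
analysis chain behind that observation: PSI quantification from
junction reads, ratio-dependent differential-splicing signatures with
3' splice-site consensus logos, allelic-ratio estimation, equilibrium
binding fits, and a proximal/distal competition rule that predicts the
direction of each splicing change from measured affinities.

Because the original cohorts (controlled-access tumour transcriptomes
and unreleased cell-line RNA-seq) cannot be redistributed, the package
ships a seeded synthetic-data generator that reproduces the statistical
structure the analysis assumes, and every claim the test suite makes is
made against that generator's known ground truth.

## The occupancy model

The generator's core is a competition model for one alternative event
with a proximal and a distal 3' splice site. Each site has apparent
association constants for the wild-type and the mutant factor. With
mutant:wild-type ratio $\rho$ and mutant fraction
$f = \rho/(1+\rho)$, the effective affinity at a site is the mixture

$$K(site) = f \, K^{mut}_{site} + (1-f) \, K^{wt}_{site},$$

and the predicted inclusion fraction of the proximal isoform is the
proximal share of total occupancy,

$$\Psi(\rho) = \frac{K(prox)}{K(prox) + K(dist)}.$$

Assumptions worth making explicit:

* **Total factor abundance is constant** across samples, so only the
  ratio matters. This mirrors the empirical finding that absolute
  mutant or total levels do not separate signature classes.
* **Mutant and wild-type factor are functionally equivalent once
  bound**; the mutation only changes binding preference.
* **The linear mixture** is the simplest dose-response form consistent
  with site competition. No quantitative dose-response curve is
  published; the mixture model is one admissible choice and is
  labelled as such. Its key property — $\Psi$ is monotone in $\rho$
  with the sign of $K^{mut}_p K^{wt}_d - K^{mut}_d K^{wt}_p$ — is
  asserted as a property test rather than assumed.

```{r}
ev <- sim_event("demo", "C", ka_wt_prox = 2, ka_wt_dist = 1,
                ka_mut_prox = 1, ka_mut_dist = 1)
occupancy_psi(ev, rho = c(0, 1, 10))
```

## What the generator emulates — and what it does not

`simulate_events()` + `simulate_cohort()` produce:

* a cohort with a minority of mutant samples (defaults: 499 wild-type,
  13 mutant, matching the proportions of the motivating tumour cohort)
  at ratios spread over 0.26–0.82, the observed range;
* per event and sample, inclusion reads drawn
  $\mathrm{Binomial}(depth, \Psi)$ at a default mean depth of 100
  informative reads, with exclusion reads the remainder;
* variant-spanning allele counts $\mathrm{Binomial}(depth, f)$;
* acceptor windows with a pyrimidine-rich tract, the invariant AG, and
  a −3 base drawn from a C-rich background (C 0.55, T 0.30, A 0.10,
  G 0.05), approximating the genomic YAG acceptor consensus;
* a "responsive" fraction of events (default 25%) whose mutant
  proximal-site affinity is shifted 3-fold in a direction set by the
  −3 base: up for −3C and −3A, down for −3T, unchanged for −3G. The
  3-fold effect size is not a published number; it was fixed once as a
  plausible magnitude for affinity changes of this kind and produces
  delta-psi shifts of 10–20 percentage points at ratio 1 — the same
  order as the reported events.

Not emulated: read-level sequencing artefacts (the generator works at
the junction-count level), overdispersion beyond binomial, tumour
purity, copy-number variation, linked events sharing reads, and
library-size differences. Passing recovery tests therefore show the
estimators are correct under clean binomial sampling, not that they are
robust to every artefact of real libraries.

Seeds are explicit arguments everywhere; identical seeds give
byte-identical outputs, and there is no hidden global random state.

## PSI quantification

`compute_psi()` is the junction-ratio estimator: inclusion-supporting
reads over all informative reads. For cassette exons inclusion is
supported by two junctions that no single read can span, so two
inclusion counts are averaged before the ratio. The upstream method the
published analysis used is described elsewhere and its exact
read-class weighting is not restated; the junction ratio is the
standard estimator and is documented here as a reimplementation
decision. PSI is undefined below `min_informative = 20` reads — the
published analysis requires "sufficient informative reads" without
printing the cutoff, so 20 is this package's configurable default.

## Signature calling and classification

`delta_psi_vs_reference()` compares one sample to the median PSI of a
reference cohort, dropping events undefined in the query or defined in
fewer than half the references. The call threshold is **inclusive** at
0.10 (a change of ten percentage points *or more*), implemented with a
$10^{-9}$ tolerance so that values like $0.5 - 0.4$ survive binary
floating-point representation. The median over an even number of
references is the midpoint of the central pair. No multiple-testing
correction is applied to per-event calls: the analysis thresholds
delta-psi, not p-values.

`build_logo()` gives per-position base frequencies and information
content $IC = 2 + \sum_b f_b \log_2 f_b$ bits (no small-sample
correction; ambiguous bases dropped per column with renormalisation).
The default window is −20..+3; only the −3 position feeds the
classifier, so the window width is cosmetic. `classify_signature()`
calls a sample *typical mutant* only when **both** discriminating
patterns hold at −3: A more frequent than T among promoted-event
acceptors, and T more frequent than C among repressed-event acceptors.
Samples showing one or neither pattern collapse to *quasi wild-type*,
matching the two-class grouping used downstream; sets smaller than 10
sequences give an undetermined call. The floor is configurable — the
published analysis does not state the event count behind "partially or
completely absent" patterns.

Group-level tests use the Mann-Whitney U (exact when
$n_a n_b \le 400$ and tie-free, otherwise normal approximation with tie
correction) or Student's pooled t test, reported as raw two-sided
p-values at $\alpha = 0.05$.

## Allelic ratio

$\rho = alt/ref$ from variant-spanning reads, with
$f = alt/(alt+ref)$; a zero reference count is an explicit infinite
ratio, excluded from correlations with a warning. For allele-sensitive
qPCR, the mutant-specific probe detects wild-type template at reduced
efficiency (an 11-fold specificity ratio in the characterisation data),
so the raw ratio $E^{\Delta Ct}$ is linearly unmixed:
$\rho = \max(0, (raw - 1/cr)\,/\,(1 - 1/cr))$. The unmixing formula is
this package's construction — only the specificity fold itself is a
published quantity — and is calibrated so a pure wild-type template
reads 0 and a pure mutant template is unchanged. Ratio–PSI association
uses Pearson's r; the anchor point (ratio 0 at the reference-cohort
median PSI) is optional and off by default, since published plots show
the anchor without stating whether it entered the printed coefficient.

## Binding fits and the competition rule

`fit_titration()` fits the two-state **ligand-depletion** isotherm —
the labelled RNA sits at fixed finite concentration, so the simple
hyperbola is wrong whenever $R$ is not negligible against $K_D$:

$$FB(P) = \frac{(P+R+K_D) - \sqrt{(P+R+K_D)^2 - 4PR}}{2R}, \quad
A(P) = A_{free} + (A_{bound}-A_{free})\,FB(P).$$

Three parameters ($K_D$, endpoints) are fit by Levenberg–Marquardt
least squares with a multistart: the midpoint-crossing concentration
plus log-spaced $K_D$ seeds spanning the titrated range, keeping the
best residual. A fit is reported `converged = FALSE` — never silently —
when the data are flat (range under $10^{-10}$), no start converges, or
the fitted amplitude is not resolved at least 3 residual-SDs above the
noise; that last rule is what flags monotone-trend-free series as
unidentifiable. Exact anisotropy corrections used in the original
instrument protocol are not restated in the source publication; the
quadratic form is documented as the reimplementation choice.

Fold changes are $\overline{K_A}^{mut}/\overline{K_A}^{wt}$ over at
least triplicate fits, tested with Welch's two-sided t on
log-transformed $K_A$ (affinities are ratio-scale). Note that at
triplicate size the Welch–Satterthwaite approximation is conservative
(empirical size ≈ 0.034 at nominal 0.05); the suite asserts level
control rather than exact size. Seven planned per-site comparisons, no
multiplicity correction, mirroring the per-site testing of the
original design.

`predict_direction()` encodes the competition rule: a significant
affinity change at exactly one site sets the direction (proximal gain
or distal loss → increased proximal use, and conversely); when both
sites change significantly, the direction follows the net fold change
$fc_{prox}/fc_{dist}$ against 1 — the "net gain" logic that explains
events where both sites lose affinity but the distal loses more. No
significant change at either site is a `no_call`, scored discordant
(conservative). Applied to the bundled direction-level encoding of the
seven experimentally titrated events, the rule reproduces 6/7
concordance, with the one deviating event being the one whose measured
affinity change opposes its observed inclusion shift:

```{r}
conc <- concordance(predict_from_table(tested_3ss_events()))
conc$table
```

## Pipeline and reproducibility

`run_pipeline()` chains
simulate → psi → signature → ratio → correlate → binding → predict
from one declarative configuration (R list or YAML), writing TSV/JSON
outputs and a manifest recording per-stage parameters, a parameter
hash, inputs, outputs and the package version — deliberately no
timestamps, so reruns with identical configuration are byte-identical.
A thin command-line wrapper lives at
`system.file("scripts", "splice-ratio.R", package = "spliceratio")`.

## Problem sizes and numerical choices in the test suite

The suite exercises the estimators at sizes chosen to make sampling
error negligible relative to the tested tolerances while remaining
quick to run: PSI recovery at depth $10^4$ over 150–200 events
(mean absolute error < 0.02), ratio recovery at allele depth $10^4$
over 200 replicates (relative bias < 2%), $K_D$ recovery from 100
noisy triplicate titrations (median relative error < 10% at noise 2%
of the dynamic range), and end-to-end signature classification on 40
simulated mutant samples (20 at ratio 1, 20 at ratio 0.05, 1500
events at depth 100; ≥ 95% must classify correctly). The
classification cohort's depth of 100 matters: it leaves enough
stochastic delta-psi calls in low-ratio samples for their logos to
clear the 10-sequence floor, which is how a ratio-0.05 sample earns a
determinate quasi-wild-type call rather than an undetermined one.

## Known limitations

* The occupancy model is deliberately minimal; kinetic and
  co-transcriptional effects, rate-limiting co-factors, and NMD
  feedback are out of scope.
* The junction-ratio PSI estimator ignores read-class weighting that a
  full event-graph quantifier would apply.
* The qPCR unmixing assumes strictly linear probe cross-talk.
* Direction-level encodings of published fold changes support the
  concordance computation but carry no replicate-level information;
  they cannot be used to re-test significance.
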