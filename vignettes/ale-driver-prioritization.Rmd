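---
title: "Simulating and prioritizing driver mutations in polyploid ALE experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and prioritizing driver mutations in polyploid ALE experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alevar)
library(dplyr)
```

## The problem

Adaptive laboratory evolution (ALE) improves a strain by serial propagation
under a selective condition — here, a mannitol-producing *Synechocystis*
derivative grown under stepwise salt stress. After the experiment, parental
and evolved clonal isolates are resequenced and the question becomes: *which
of the hundreds of called mutations actually drove the gain?*

Two properties of this system make naive filtering fail:

* **Polyploidy.** *Synechocystis* carries on the order of ten chromosome
  copies per cell. A mutation present in only some copies of a clonal
  isolate yields a read-support fraction strictly between 0 and 1 (for
  example 0.745 or 0.371), so variant callers must be run in polymorphism
  mode — which in turn inflates the number of low-frequency false-positive
  calls dramatically.
* **Hitchhiking and drift.** Standing neutral variation and passenger
  mutations rise and fall with the lineages that carry them, so frequency
  changes alone over-call candidates.

`alevar` packages the full inference chain — polymorphism-frequency tables
in, ranked candidate genes out — together with a ground-truth simulator that
lets the chain be tested end to end.

## The prioritization procedure

The central object is the **frequency matrix** `F` (mutations × isolates) of
read-support fractions, with isolates labelled *parental* or *evolved*;
absent observations are 0 because polymorphism callers omit what they do not
see. Two independent evidence channels are computed:

1. **PCA channel.** Isolates are observations and mutations features.
   Features are centered but *not* rescaled — every entry is already a
   fraction on the same scale, and rescaling would blow up the many
   near-constant false-positive rows. Components come from the SVD of the
   centered matrix; loadings are unit-norm and each component's sign is
   fixed so its largest-magnitude loading is positive. A component is kept
   when its scores *discriminate the groups*: the absolute difference of
   group-mean scores divided by the pooled within-group standard deviation
   must reach `tau` (default 1.0; zero spread with distinct means counts as
   infinite separation). Group separation was judged from score plots in the
   original workflow; the separation statistic formalizes that judgement so
   the pipeline can run unattended. From each selected component the `k = 10`
   largest-|loading| mutations are taken, ties broken by lexicographic
   mutation id.
2. **Enrichment channel.** For each mutation, its mean frequency in the
   parental and evolved groups and `delta = evolved − parental`. A mutation
   is *increasing* when `delta > 0`, strictly: this is a marking step, not a
   hypothesis test, so no effect-size floor and no multiple-testing
   correction are applied. A **gene-exclusion rule** then discards every
   mutation in any gene that also contains a mutation with `delta < 0` —
   a gene whose alleles move in both directions cannot cleanly explain a
   gained phenotype. Intergenic mutations are outside this rule's scope.

A gene becomes a candidate when it holds a top-loading mutation **and** an
increasing, filter-surviving mutation (`combine = "intersection"`, the
default — the two mutations may differ, as when one allele of a gene
dominates a component while another rises); under `"union"` either channel
suffices. Candidates are ranked by largest `delta`, then largest |loading|.

## The simulator and what it emulates

`simulate_ale()` is a lineage-based Wright–Fisher model of growth–dilution
cycles. Each transfer grows the culture from OD730 0.05 to ~2.0, i.e.
`g = log2(40) ≈ 5.32` generations, and consists of:

* **Selection** — lineage abundances are reweighted by `w(salt)^g` with
  `w = prod(1 + s_m(salt) · c_m)` over carried mutations; driver
  coefficients scale linearly with salt above a reference concentration
  (default 100 mM), reflecting a benefit tied to the perceived intensity of
  the stress.
* **Mutation** — a Poisson number of new mutations (default 3/transfer)
  found daughter lineages of one cell, entering at copy fraction `1/P`.
* **Polyploid segregation** — every partially segregated copy fraction is
  resampled once per generation as `Binomial(P, c)/P`. This neutral
  intracellular drift is the simplest mechanism producing the partially
  segregated clonal frequencies (0.745, 0.371, …) that motivate polymorphism
  mode; 0 and 1 are absorbing.
* **Bottleneck** — a multinomial sample of `N_b` cells (default 10,000)
  emulates the dilution; `infinite_bottleneck = TRUE` gives the
  deterministic limit used by the exactness tests.

Under a stepwise schedule the simulator applies the same salt-step rule
exposed as `salt_step_controller()`: +50 mM (capped at 400 mM) once the
population growth rate has stabilized at or above the rate reached at the
end of the previous level. The population rate is phenomenological —
reference rate 0.052 h⁻¹, a linear osmotic penalty of 0.15 per 100 mM above
the start, times the population mean fitness — and exists to drive the
controller, not to model physiology. The experimental protocol phrases the
step rule two ways ("equal to or larger than" the previous end rate, and
"increased or stabilized"); the ≥-previous-end form is implemented. No
numeric stabilization criterion is stated anywhere, so `is_stabilized()`
flags a <5% relative change between successive estimates; that threshold is
this package's choice.

### The default scenario and its rationale

The defaults of `ale_config()` are the package's study conditions:

* **10 standing parental lineages**, each with **18 private neutral
  mutations** at copy fractions drawn from the `1/P` lattice. Three picked
  parental colonies then carry ~50 observed neutral mutations across ≥20
  genes — the scale of real polymorphism-mode call sets (hundreds of
  mutations in tens of genes).
* **One adapted founder lineage at abundance 0.02** carrying one fully
  segregated driver mutation in each of the two configured driver genes.
  Planting both drivers in one lineage mirrors evolved isolates that carry
  mutations in two genes simultaneously; starting them fully segregated
  makes the planted signal a property of the scenario rather than of
  intracellular drift luck. Standing neutral mutations are placed in
  non-driver genes so that gene-level ground truth is unambiguous.
* **False positives at ~20 per isolate**, at distinct never-reused positions
  drawn uniformly over a 3.5 Mb replicon of which <1% is genic, with
  frequencies from Beta(1, 9). Real mutations are placed inside genes; false
  positives land mostly intergenic, as scattered one-off calls do.
* **Depth 100** binomial read sampling; calls with zero supporting reads are
  absent, as a caller would report.

What the generator does *not* emulate: linkage to real genome structure,
mutation-spectrum biases, caller-specific error modes (strand bias,
homopolymer indels), coverage variation, or any physiological coupling
between mannitol flux and fitness. A pipeline that recovers planted drivers
here is validated for its *logic* — matrix construction, PCA selection,
enrichment, exclusion, combination — not for robustness to alignment
artifacts.

## Numerical choices and degenerate inputs

* Frequencies serialize with 4 decimals (the precision of percentages like
  74.5%); round trips are exact at that precision.
* Coordinates are 1-based inclusive throughout; BED input is converted on
  ingest. Overlap assignment ignores strand, and ties go to the gene with
  the smaller start, then lexicographic id.
* A frequency matrix with no varying mutation is a degenerate PCA input and
  errors explicitly rather than returning arbitrary axes.
* `run_pca()` keeps components with singular values above `1e-12` of the
  largest; variance fractions are eigenvalue shares of total feature
  variance, so they sum to ≤ 1.
* Growth rates come from OLS on `ln(OD)` over the whole window, no window
  search: the protocol samples inside the exponential phase by design. For
  a noiseless exponential the slope is recovered to machine precision. With
  1% multiplicative OD noise sampled every 2 h over 10 h the slope error is
  unbiased with standard deviation `0.01/sqrt(70) ≈ 0.0012 h⁻¹` — an
  information-theoretic floor (OLS on logs is efficient here) worth keeping
  in mind when comparing rates in the 0.03 h⁻¹ range, where 5% relative
  error is only ~1.4 of those standard deviations.
* Poisson/binomial/multinomial draws all come from R's global generator,
  seeded once per entry point; the pipeline derives per-stage child seeds
  from the master seed so stages can be re-run reproducibly.

## Worked example

```{r example}
run <- run_ale_pipeline(seed = 11)
run$scorecard
tidy(run$report)
```

The simulator's trajectories and the isolate-space PCA can be inspected
directly:

```{r plots, fig.width = 6, fig.height = 4}
autoplot(run$sim)
fm <- build_matrix(run$observations, attr(run$observations, "isolates"))
autoplot(run_pca(fm))
```

## Problem sizes used in validation

The test suite exercises the default 20-transfer scenario across 100 seeds
for end-to-end recovery, 1000 random 6×20 matrices against a covariance
eigendecomposition oracle, the complete 3⁹ enumeration of delta-sign
patterns for the exclusion filter, 1000 noisy growth curves per reported
rate, 1000 single-transfer neutral replicates plus 100 strong-selection
trajectories against the closed-form recursion, and 30 randomized
round-trip record sets per format. These sizes give stable statistics at
desk scale; all are plain function arguments and scale up freely.

## Known limitations

* Selection acts between lineages only; within-cell copy-number dynamics are
  strictly neutral. Dosage-dependent selection *within* cells (gene-dosage
  sweeps) is not modelled, though lineage-level selection on the dosage-
  weighted fitness captures its first-order effect.
* The candidate report is gene-level; intergenic and regulatory candidates
  are visible in the evidence table but never ranked.
* `combine = "intersection"` reproduces a small, conservative final set;
  `"union"` is provided because the underlying procedure's combination step
  is described only loosely, and real analyses should look at both.
* Precision of the report is undefined (NA) when the report is empty.
```
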