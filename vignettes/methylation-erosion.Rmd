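---
title: "Division-coupled methylation erosion: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Division-coupled methylation erosion: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replitali)
```

This vignette is the package's own account of the science it implements:
the erosion model and its assumptions, the conventions and tunable
parameters, what the simulator does and does not emulate, and the choices
made where the design was genuinely open.

## The phenomenon and the model

Partially methylated domains (PMDs) are large, late-replicating genomic
regions whose CpG methylation decays with cumulative cell division. The
decay is sharpest at *solo-WCGW* CpGs — an A or T immediately on both sides
of the CpG, and no other CpG within 35 bp — because maintenance
re-methylation after DNA replication is least efficient in exactly that
context. The package treats a bulk culture's fractional methylation at one
CpG as a per-division recursion:

$$\beta' \;=\; \beta(1-r) \;+\; g\,\bigl(1 - \beta(1-r)\bigr),$$

where $r \in [0,1)$ is the probability per division that a methylated CpG
fails to be re-methylated and $g \in [0,1)$ the probability that an
unmethylated CpG acquires methylation de novo. The map is affine with slope
$(1-r)(1-g)$, so trajectories approach the equilibrium

$$\beta^\* \;=\; \frac{g}{1-(1-r)(1-g)}$$

geometrically, which is the plateau a telomerase-immortalised culture
reaches when compensatory de novo methylation finally offsets further loss.
`step_methylation()`, `equilibrium_beta()` and the simulator's internal
closed form all share this single model. An equivalent equilibrium-driven
interpretation — plateau by selection against further loss rather than by
per-site balance — cannot be distinguished from bulk data; the simulator
implements the per-site equilibrium model only.

Assumptions worth stating: methylation states are treated as bulk means
(no cell-to-cell heterogeneity, no selection in culture); rates are
constant per division for a given CpG; divisions act multiplicatively and
time enters only through a minor repair-synthesis term (below).

## Conventions and tunable parameters

* **Solo distance.** Distance is start-to-start between the C positions of
  neighbouring CpGs, and the threshold (default 35 bp) is
  boundary-inclusive: a nearest neighbour exactly 35 bp away is solo.
  Whether the original definition measured gap length or start-to-start
  distance is not documented anywhere we know of; this package fixes the
  start-to-start convention and exposes the threshold as an argument rather
  than guessing an intent.
* **Coordinates.** 0-based half-open everywhere internally; BED is consumed
  natively; probe manifests declare their base (`manifest_base`) and are
  converted on import. Only the CpG's C position is tested for interval
  membership.
* **Strand.** Plus-strand representation only: CG is its own reverse
  complement and W/S flank classes are mirror-symmetric, so
  strand-duplicated records would be redundant (a property the test suite
  checks explicitly).
* **N flanks** make a CpG `ambiguous` and keep it out of WCGW/SCGS sets;
  guessing a flank class would contaminate the very contrast the classes
  exist for.
* **Population doublings.** `PD = 3.32 (log10 Y − log10 I) + X` with the
  constant written as the field writes it (3.32, not `1/log10 2`); chaining
  passages is exactly additive in log growth ratios.
* **M-values** use base-2 logit with clipping at `eps = 1e-6`, the
  methylation-array convention; slopes and effect sizes are reported on the
  β scale (interpretable as fractional methylation per PD), hypothesis
  tests run on the M scale where variances are more homogeneous.
* **CpG categories.** "Variable" means more than a 0.10 absolute change
  between the earliest-PD and latest-PD anchors (replicate samples at the
  anchor PD averaged, so parallel subcultures are tolerated). The stable
  groups' starting-β bounds are not pinned down by any published rule;
  defaults 0.70/0.30 are an exposed convention, and a stable probe whose
  start falls between them is assigned to the nearer bound rather than
  silently dropped, keeping the partition exhaustive.
* **Slope comparisons.** The published analyses used mixed-effects models
  with Tukey contrasts. `compare_slopes()` deliberately replaces this with
  a fixed-effects OLS interaction test on M-values, with the subculture as
  an optional fixed covariate: with a handful of parallel subcultures the
  random-effect variance is barely identified, while the fixed-effects
  interaction F test answers the same question (do slopes differ between
  conditions?) with transparent degrees of freedom. The degenerate case of
  two identical groups returns an estimate of 0 with p = 1.
* **Replication timing.** Six-fraction signals are percent-normalised
  before weighting, the usual convention for these profiles, making the WA
  score invariant to sequencing depth. Weights 0.917, 0.750, 0.583, 0.417,
  0.250, 0 place the score in [0, 0.917], higher = earlier.
* **Clock training.** Elastic net with α = 0.5; the penalty is chosen by
  10-fold cross-validation at the minimum mean CV error, with seeded folds
  (fold counts shrink to keep ≥ 3 observations per fold on small reference
  sets). No published penalty-selection rule or fold count exists for the
  procedure this reproduces, so both are configurable defaults. Features
  are standardised internally; coefficients are reported on the β scale.
  The train/test split is simple random over samples; stratification by
  cell line is available but off by default. At application time missing
  clock probes are a hard error unless mean-imputation is requested
  explicitly — reduced arrays under-represent solo-WCGW CpGs, and silent
  imputation would hide exactly that drift.

## What the simulator emulates

`sim_config()` + a scenario constructor define a synthetic EPIC-like
experiment:

* **Probe panel** (drawn once from the config seed, shared across
  scenarios): four context classes with per-division rates ordered
  `r(soloWCGW-PMD) > r(social-PMD) > r(non-PMD)`, defaults
  `r = 0.009, 0.004, 0.0015, 0.0002` and `g = 0.0008, 0.0008, 0.0005,
  0.002`, starting β ≈ 0.85 (0.80 for social non-PMD). These defaults
  reproduce the qualitative erosion orderings (solo-WCGW fastest; social
  non-PMD drifting slightly upward) and a plateau within a few hundred
  doublings of immortalised culture. Per-probe modifiers: a mean-one
  lognormal jitter (sd 0.25); replication-timing coupling
  `1 + κ(0.917 − WA)/0.917` with κ = 0.5 (PMD probes draw late WA,
  non-PMD early); and an expression-protection factor `1 − e` (e = 0.5) on
  a 15 % gene-linked subset. The panel holds 3000 probes
  (1200/1000/400/400) — a ~30-fold scale-down of a realistic common-PMD
  pool that keeps clock-estimate noise in a realistic regime while training
  in seconds.
* **Dynamics per passage**: whole divisions applied exactly via the affine
  closed form, the fractional remainder as a linearly scaled partial step
  (keeping the sample sheet's yield/inoculum bookkeeping exactly
  invertible); plus a small per-day loss for unscheduled, repair-associated
  DNA synthesis (default 2×10⁻⁴/day at ambient oxygen, quartered under low
  oxygen), scaled per probe by its maintenance vulnerability relative to
  the solo-WCGW class — repair patches are re-methylated by the same
  machinery, so robust contexts are barely touched and the slight de novo
  gain at social non-PMD CpGs survives ambient-oxygen culture.
* **Observation noise**: a mean-preserving beta law with precision ν = 100
  (β-sd ≈ 0.03–0.05 mid-range), chosen over additive Gaussian noise to
  respect the [0, 1] bounds; `Inf` disables it. Exact values are kept in
  the truth tables.
* **Scenarios**: `scenario_standard()` — seven lineages with distinct
  in-vivo starting offsets (15–45 PD), 26 passages of ~2 PD (≈ 52 PD, a
  primary lifespan), ~182 samples; `scenario_serum()` — one line at four
  serum levels with division rates (1, 0.7, 0.45, 0.25) over 22 weekly
  passages, equal elapsed time but diverging doublings, which is what lets
  time and division be disentangled; `scenario_arrest()` — an arrested arm
  (PDs frozen, collections at days 18 and 25) against a proliferating
  control arm per cell line; `scenario_immortalized()` — one lineage driven
  ~430 PD so the plateau is actually reached. Problem sizes are chosen so
  the whole simulated panel trains and evaluates in seconds.

What it does **not** emulate — and therefore what passing tests do not
show about real data: probe-level technical artefacts (detection failures,
cross-hybridisation, batch effects), cellular heterogeneity and selection,
transcriptional feedback on rates, absolute rate calibration to any real
cell type, and senescence-associated biology beyond the scheduled halt of
divisions. The simulator validates the machinery, not the biology's
parameter values.

## Numerical choices and degenerate inputs

Equilibrium checks run at machine precision (the fixed point of the affine
map is exact to ~1e-15); equality of the iterated map with the closed form
is asserted at 1e-12. The all-zero Repli-seq profile yields NA with a
warning rather than an error, since real bins can be empty. The
zero-variance cases all have defined answers: identical pre/post samples
give p = 0.5 (one-sided), duplicated groups give a slope difference of 0
with p = 1, a contig's only CpG is solo at infinite distance. Quantile
bins use equal counts with ties broken by order. Clock determinism is
bit-exact given config and seed; train/test splits, CV folds and the probe
panel all derive from explicit seeds.

In the test suite, the slope-recovery property compares fitted slopes with
their noise-free targets at a two-standard-error radius; the nominal
normal coverage of that radius is 95.4 % and finite-df t coverage slightly
less, so the assertion allows binomial slack below 95 % rather than
pretending the radius is exact.

## Known limitations

* The erosion model is first-order per division; it cannot represent
  replication-uncoupled maintenance catching up over multiple cell cycles,
  only its net per-division effect.
* The clock's PD normalisation inherits the reference model's
  extrapolation error for lineages whose starting age lies far outside the
  reference culture's observed range.
* `compare_slopes()` is a fixed-effects approximation; with many parallel
  subcultures per condition a genuine mixed model would be more efficient.
* Composition reporting for a published coefficient set requires that
  coefficient file and a genome-wide context annotation as inputs; neither
  ships with the package.
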