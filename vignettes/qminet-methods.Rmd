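---
title: "Methods: calling dynamic protein interactions from multiplexed bead data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling dynamic protein interactions from multiplexed bead data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qminet)
```

## The measurement and its data model

Quantitative multiplex co-immunoprecipitation (QMI) captures many protein
targets on antibody-coupled flow-cytometry beads and probes each captured
complex with labeled detection antibodies. The unit of measurement is the
ordered pair `IP_probe`: the protein immunoprecipitated on the bead and the
protein detected on it. The roles are not symmetric — `AKT_mTOR` and
`mTOR_AKT` are different measurements — and self-pairs (`AKT_AKT`) report
apparent abundance rather than an interaction. Each `IP_probe` in each well
yields a *distribution* of typically 50–150 bead fluorescence reads; each
sample is measured in two duplicate wells; samples come in matched
control/treated pairs from the same biological replicate, processed
identically, so that pairwise differences isolate the acute effect of the
manipulation (the starve/refeed paradigm is the motivating design: serum
starvation quiets signaling, refeeding reactivates it).

`qminet` keeps everything tabular. Bead events, sample metadata and coded
hypotheses ("traits") are tibbles read from plain CSV; the
interactions-by-samples summary is a `qmi_mfi` tibble carrying a
linear/log2 scale flag. Two summaries coexist deliberately:

* **MFI matrix** — per (interaction, well) the *median* fluorescence (the
  Luminex-standard MFI), then the arithmetic mean of the two duplicate-well
  medians on the linear scale. This feeds the network analysis and all
  fold-change reporting.
* **Bead distributions** — the raw per-well read vectors, which the ANC
  route compares directly without collapsing.

Interactions whose median MFI across all samples falls below 100
fluorescence units are removed as noise before either route runs. The
filter keys on the per-interaction median (not the mean or minimum) to stay
consistent with the pipeline's robust-summary style, and it runs after
duplicate averaging; both choices matter only for interactions straddling
the cutoff.

## Route 1: adaptive nonparametric comparison (ANC)

For each retained interaction and each matched pair, the duplicate wells of
each sample are pooled and the two bead distributions compared with a
two-sample Kolmogorov–Smirnov statistic,
$D = \sup_x |F_{\mathrm{treated}}(x) - F_{\mathrm{control}}(x)|$,
computed exactly over the pooled step points (ties handled by integer
cumulative counts). The p-value uses the asymptotic Kolmogorov distribution
at effective size $n_e = n_a n_b/(n_a + n_b)$; with ≥ 50 reads per well the
asymptotic regime is appropriate, and exact small-sample p-values are
deliberately out of scope. KS was chosen because it compares whole
distributions on the raw fluorescence scale with no distributional
assumptions and is invariant under monotone transforms — calibration
curves, log scaling, and gain settings cancel out.

**Empirical alpha.** Testing ~10²–10³ interactions over several pairs
requires multiplicity control, but bead data violate the independence
assumptions behind a nominal Bonferroni level in both directions. The
calibration therefore starts at $\alpha_B = \alpha/m$ (m = interactions
tested) and checks it against comparisons that are *known to be null in
every experiment*: the two technical duplicate wells of the same sample.
If more than a fraction $\alpha$ of those null comparisons fall below
$\alpha_B$, the cutoff is stepped down through the sorted null p-values to
the largest level at which the null exceedance stays within $\alpha$. With
no usable nulls (or fully tied ones, where no step level exists) the
Bonferroni level is used and a warning logged. The calibrated level
$\alpha^* \in (0, \alpha]$ is reported with every result.

**The hit rule.** An interaction is an ANC hit when strictly more than 70%
of its matched pairs are significant at $\alpha^*$ *and* share the modal
direction of change among the significant pairs (direction = sign of the
treated-minus-control median shift). "Strictly more" means f = 0.70 exactly
is not a hit. Significant pairs that contradict the modal direction count
against the numerator but stay in the denominator — consistency is part of
the evidence, not a reason to discard comparisons. Per interaction the
median across pairs of the pairwise log2 MFI ratio is reported as the
effect size.

## Route 2: correlation network analysis (CNA)

CNA consumes the log2, batch-corrected MFI matrix (a configuration switch
admits linear input for sensitivity checks). Batch correction is the
parametric empirical-Bayes location/scale model — normal prior on
per-batch offsets, inverse-gamma on scale factors, moment-matched
hyperparameters, iterative refinement to 1e-4 — with the condition labels
protected as a covariate, delegated to `sva::ComBat()`. A single batch
passes through unchanged; a batch with one sample is an error unless
mean-only adjustment is requested (its scale is not estimable); a condition
inseparable from batch degrades to covariate-free correction with a
warning, since the correction may then absorb real effects.

The network is the unsigned power adjacency $a_{ij} = |\mathrm{cor}(x_i,
x_j)|^\beta$. Unsigned is the historical default of the power adjacency
function and keeps rising and falling interactions of one program in one
module; the cost is that the membership statistic kME can be negative for
anti-correlated members, and the hit gate (below) requires kME > 0. The
power β is selected as the smallest candidate (1–20) whose connectivity
distribution approximates scale-free topology with signed fit
$-\mathrm{sign}(\mathrm{slope})\cdot R^2 \ge 0.8$ (falling back to the
maximizing power): connectivity k is binned into 10 equal-width bins over
its range and mean log10 frequency is regressed on mean log10 connectivity.
Equal-width binning makes the frequency profile informative; the fit table
is returned for inspection. On panels much below ~10² informative nodes the
fit index is noisy and can drift to powers where the network degenerates
(mean connectivity ≪ 1); benchmark analyses at that scale fix β = 6, the
conventional unsigned default, and the automatic choice is verified
separately against an independent recomputation of the fit table.

Topological overlap
$\mathrm{TOM}_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$
with $\ell_{ij} = \sum_{u\neq i,j} a_{iu}a_{uj}$ smooths the adjacency by
shared neighbourhoods; modules are cut from the average-linkage dendrogram
of $1-\mathrm{TOM}$ at a fixed fraction (default 0.9) of the maximum merge
height. A static cut was preferred over dynamic hybrid cutting: it is
deterministic, has two interpretable parameters, and suffices at panel
scale; dynamic cutting is the documented extension point. Clusters smaller
than `min_size` (default 5) become `grey`/unassigned; the rest take the
conventional color names in decreasing size order, deterministically. Merge
heights below 1e-10 are treated as ties of identical profiles.

Each module is summarized by its eigenvector: the first right singular
vector of the z-scored member × sample matrix, unit norm, sign-oriented so
its mean correlation with member profiles is positive (ties: positive first
coordinate). Module–trait association is the Pearson correlation between
eigenvector and coded hypothesis with the exact t-transform p-value
$t = r\sqrt{(n-2)/(1-r^2)}$ on n−2 degrees of freedom; module membership
(kME) uses the same transform on the interaction-profile/eigenvector
correlation. Constant profiles are dropped (eigenvector) or given zero
correlation (adjacency) with warnings; constant traits are rejected at
validation because their correlation is undefined.

## Intersection and reporting

Modules whose eigenvector correlates with the chosen hypothesis at
p < 0.05 are modules of interest; CNA hits are interactions with
membership p < 0.05 and kME > 0 in such a module; the high-confidence set
is the intersection with ANC hits, and the containment is asserted on
every pipeline run. Reported alongside: log2 fold changes on group means of
linear MFI (means, not medians, so planted multiplicative effects are
recovered without bias under the simulator's algebra), row-median-scaled
values (each interaction divided by its across-sample median, giving
row-median exactly 1 and unitless comparability across baselines spanning
two orders of magnitude), module activity (per-sample mean of member
scaled values, tested by one-way ANOVA plus pairwise Welch t-tests with
Bonferroni correction over the tested pairs, matching the reporting style
of the figures this mirrors), PCA of samples (interaction-centered SVD via
`prcomp`), average-linkage sample clustering on correlation distance
(columns pre-sorted lexicographically so ties resolve deterministically),
and a Cytoscape-compatible edge list in which self-interactions are
retained but flagged as abundance nodes.

## The simulator: what it emulates and what it does not

`simulate_qmi()` draws a full experiment from an explicit generative model.
Per interaction g a baseline $\mu_g$ is log-uniform on 150–20,000
fluorescence units (the dynamic range of a typical panel). The expected
level of sample s (condition c, replicate r, batch b) is
$$m = \mu_g \cdot 2^{e_{g,c}} \cdot \rho_{g,r} \cdot \beta_{g,b},$$
with log-normal replicate multipliers (CV 0.10), per-interaction batch
multipliers (0.25 log2 s.d.), a shared per-well pipetting multiplier
(CV 0.05; shared across the panel because a well is pipetted once), and
log-normal bead noise with CV 0.30 around arithmetic mean m — the
mean-parameterization makes planted log2 effects exact in expectation of
the mean, while the reported MFI (a median) differs only by a constant
factor $\sqrt{1+\mathrm{CV}^2}$ that cancels from every contrast. Bead
counts are uniform integers in 50–150 per interaction per well, in
duplicate wells. Replicates are assigned whole to batches, split evenly,
so batch never confounds condition. The trait table carries one 0/1 row
per non-reference condition plus optional ordinal codings (e.g. minutes
since refeeding). Defaults — 384-interaction panel, 8 biological
replicates, planted effects in the 0.1–0.5 log2 range — mirror the scale
of the assay this package analyzes. Ground truth (module membership,
expected effects, every nuisance multiplier drawn) is returned and
serializes losslessly to JSON; identical config and seed give bit-identical
output.

What the simulator does *not* model: background-bead subtraction and
inter-well normalization (assumed already applied upstream), heavy-tailed
or multi-modal bead populations, saturation at the detector ceiling,
correlated antibody cross-reactivity, and any mechanistic kinetics —
effects are planted per condition, not generated from signaling dynamics.
Passing tests therefore demonstrate statistical correctness of the
pipeline under a realistic noise budget, not robustness to every artifact
of real bead arrays.

## Verification design and problem sizes

The package is verified at three levels, all runnable on one CPU in
minutes. Exact oracles: the KS statistic against exhaustive sup-ECDF
enumeration over all tied samples of size ≤ 6 on {0,1,2,3}; TOM against
triple-loop summation on 1,000 random 8-node networks; eigenvectors
against direct SVD; correlation p-values against the closed form
(including r = 0.83 at n = 28, where p ≈ 4.7e-8); average linkage against
a naive O(n³) agglomerator. Calibration properties: ANC type-I error on
null simulations (200 interactions, 4 pairs, 100-bead wells, 50 seeds;
mean hits per run well under 1), sensitivity on a planted log2FC grid
0.1/0.2/0.4/0.8 (10 seeds each; ≥ 0.8 at 0.4 and monotone in effect and
bead count), and batch-correction residuals on a planted
two-batch offset (0.5 log2 location, 1.5× scale, residual noise s.d. 0.08
log2 with 32 samples per batch — sized so the empirical-Bayes shrinkage
residual, of order σ√(2/n), is what the < 0.05 criterion actually
measures). End-to-end: two planted trait-linked modules (10 + 10
interactions, +0.5 log2 on refeeding — the top of the realistic effect
range, where both routes should be near-saturated) in a 120-interaction
panel at 8 replicates, requiring ≥ 80% recall at ≤ 5% false discovery in
at least 8 of 10 seeds, an empty or single-call high-confidence set under
the null, and byte-identical artifacts across repeated seeded runs. The
same computations are scripted in `scripts/acceptance.R`.

## Known limitations

* The empirical alpha calibrates against duplicate-well nulls, which share
  sample-level biology; replicate-level nuisance that does not appear
  within samples is invisible to the calibration (though it is absorbed by
  the matched-pair design).
* Unsigned networks merge anti-correlated programs into one module; the
  kME > 0 gate then admits only the majority-sign members. A signed
  adjacency would be the natural extension.
* The static tree cut has no notion of nested modules; deeply nested
  structure requires dynamic cutting.
* Asymptotic KS p-values are anti-conservative below ~25 reads per side;
  the pipeline assumes bead counts in the assay's normal range.
* Self-interactions pass through all statistics unchanged; interpreting
  them as abundance is the analyst's responsibility.
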