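---
title: "methpanel: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methpanel: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical model behind each stage, the
parameters that matter, and the choices made where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The pipeline at a glance

Input is a probes × samples matrix of beta values (methylated signal
fractions in [0, 1]) plus a sample sheet mapping samples to individuals,
tissue class (AB = subcutaneous abdominal adipose, OM = omental adipose)
and timepoint (before/after weight loss). The discovery chain
(`run_discovery()`) is:

1. **merit + Wilcoxon filter** (`candidate_filter()`) — per-site class
   separation score and paired signed-rank test;
2. **sample graph + clique homogeneity** (`build_sample_graph()`,
   `maximal_cliques()`, `homogeneity_check()`) — a diagnostic that the
   candidate panel clusters samples by tissue;
3. **coverage + red/blue dominating set** (`coverage_relation()`,
   `redblue_dominating_set()`) — removes sites whose information is
   carried by others;
4. **separation evaluation** (`separation_report()`, `reduce_panel()`) —
   within- vs between-class inter-sample score distributions for the full
   shortlist and reduced top-k / top-1 panels.

## Merit and the Wilcoxon gate

`merit = |median(A) − median(B)| − (sd(A) + sd(B))`, on the beta scale.
Medians resist the occasional outlying sample; subtracting both
within-class SDs means merit > 0 roughly when the class supports are
separated by more than their combined spread. Merit is
translation-invariant and scales linearly under positive scaling — it is a
separation margin, not a test statistic.

The candidate gate additionally requires a paired Wilcoxon signed-rank
P < 0.001 (`p_threshold`). The test is paired across individuals (AB vs OM
of the same person), the natural reading for a within-individual design.
Zero differences are dropped (classic handling; it keeps the exact
enumeration simple and is the conservative choice for bounded beta data
where exact zeros are rare). For effective n ≤ 25 the exact null
distribution of the positive-rank sum is built by convolution over the
observed rank multiset — identical to enumerating all 2^n sign
assignments, which the test suite verifies against a literal 2^n oracle
for n ≤ 12. Consequences of exactness worth knowing: with unanimous
direction the two-sided p is 2·2⁻ⁿ, so the 0.001 filter is attainable only
from n = 11 pairs upward; at the design size n = 15 it is 6.1×10⁻⁵. Above
n = 25 a normal approximation with tie-corrected variance
(`sum(r²)/4`) and a 0.5 continuity correction takes over.

## Sample graph and clique homogeneity

Similarity between samples p, q over a panel is
`w(p,q) = 1 − mean |β_p − β_q|` (missing probes pairwise-deleted). The
metric is bounded in [0, 1], directly interpretable on the beta scale, and
monotone in class separation; a correlation-based alternative
(`metric = "correlation"`) is available since no canonical metric is
mandated by the approach. The graph is built on the top-`panel_m` merit
sites (default 100 — large enough to average out single-probe noise, small
enough that weak candidates do not dilute the signal).

The threshold applied before clique enumeration defaults to the midpoint
between the mean within-class and mean between-class edge weights
(`graph_threshold = "auto"`). This step is a *diagnostic* — class labels
exist and the question is whether the panel reproduces them — so using the
labels to set the threshold is legitimate; a fixed numeric threshold can
be supplied instead. Maximal cliques are enumerated with Bron–Kerbosch
pivoting (verified against full subset enumeration on small graphs), and a
clique is homogeneous when all members share a tissue. Cliques below
`min_clique_size = 3` are ignored in the overall verdict: a size-2 clique
is a bare edge and carries almost no clustering evidence. A failed
homogeneity gate does not abort the pipeline; it is recorded in the run
summary so callers can distinguish the outcome, since the downstream
reduction is still well-defined.

## Coverage and the dominating set

The reduction needs a "u covers v" relation; redundancy between two
markers is read as profile agreement: `|Pearson r| ≥ τ` across samples,
default `τ = 0.9` (high enough that a covered site is genuinely
substitutable, low enough that noisy replicates of the same signal
collapse). Absolute correlation is used because an anticorrelated probe
carries the same discriminating information with the sign flipped.
Zero-variance probes cover only themselves. τ is recorded in the output.

With red (allowed dominators) and blue (sites to cover) both equal to the
candidate set, red/blue dominating set reduces to classical dominating set
on the cover graph. Instances with at most `exact_limit = 20` candidates
are solved to optimality: nodes dominated only by themselves are forced
first, then an increasing-cardinality subset search (feasible at this
scale; candidates are ordered by merit, so among equally small solutions
the search prefers high-merit sites). Larger instances use greedy set
cover — most new coverage first, merit then probe id breaking ties — which
is always feasible and carries the classical (1 + ln n) bound, checked in
the suite. Selected sites are reported in merit order, so "top 10" and
"top 1" reduced panels are well defined.

## Separation evaluation

The inter-sample score reuses the `1 − mean|Δβ|` form. *Complete
separation* requires every between-class pair to score strictly below
every within-class pair — ties count as overlap (conservative). Histograms
are fixed-width on [0, 1] (`bins = 30`) with edges exported, since only
the relative positions of the within/between distributions are
meaningful.

## Traditional differential methylation

Paired t tests on per-individual AB − OM differences, by default on the
beta scale, which keeps reported means and Δbeta directly interpretable;
`scale = "mvalue"` applies the logit₂ transform (with clipping bound
`epsilon`) first, the variance-stabilised alternative. "Bonferroni-adjusted
P ≤ 1×10⁻⁷" is read literally: `p_adjusted = min(1, p_raw · n_tests)` is
compared to the threshold, with `n_tests` the number of probes that
survived missingness filtering (logged). Probes with fewer than
`min_pairs = 3` complete pairs or zero-variance differences are dropped
with counts reported. Two rankings are provided (adjusted p ascending;
|Δbeta| descending) plus signed Δbeta bin summaries at thresholds
{0.05, 0.10, 0.20, 0.50} and the two-timepoint overlap report flagging
probes whose |Δbeta| widened by ≥ `widen_min = 0.05` after weight loss.

Sign conventions, fixed package-wide: Δbeta = mean(AB) − mean(OM);
Δtrait = value(before) − value(after), so weight loss yields positive
changes for weight-like traits. The Pearson screen
(`correlation_screen()`) tests each probe's per-individual Δbeta against
each Δtrait and filters on raw p ≤ 0.001 with no multiplicity correction —
that is the screen's definition, and the output notes it. No adjustment
for covariates (e.g. diabetic status, gender) is attempted.

## The synthetic cohort: what it does and does not emulate

`simulate_cohort()` draws each observation from a beta distribution with
mean `inverse-logit(logit(tissue mean) + individual effect)` and
concentration `precision`. It emulates, with defaults chosen to mirror the
motivating study's stated world:

* **design**: 15 individuals × 2 tissues × 2 timepoints (60 arrays);
* **bimodality**: probe baselines drawn from a two-mode mixture (modes
  0.15/0.85, equal weight) — array probes cluster near un- and
  fully-methylated;
* **within-individual correlation**: a shared logit-scale random effect
  per individual (`individual_sd = 0.15`);
* **planted markers**: `n_discriminating` probes with tissue deltas
  `delta_levels` (defaults 0.4/0.6, the magnitude of the study's top
  sites) on the mean scale, clipped to [0.02, 0.98]; feasibility is
  checked against the *widened* after-timepoint shift
  (`delta_widen = 1.3`, reflecting roughly twice as many significant sites
  after weight loss) and baselines are re-anchored rather than silently
  clipped, so recorded truth deltas are exact;
* **probe noise**: `precision = 200` gives per-probe SDs of ±0.02–0.04 at
  mid-range means, the scale of the (±SD) values printed for the study's
  top markers;
* optionally a **trimodal SNP-disrupted probe** (genotype drawn at the
  configured allele frequency, methylation set per genotype) and **traits**
  constructed as `r·z + noise_sd·ε` around a named probe's standardised
  per-individual Δbeta, so the empirical correlation converges to the
  target `r` (and to 1 as `noise_sd → 0`).

It does **not** model probe cross-hybridisation, batch effects, cell-type
admixture, or genomic autocorrelation between neighbouring CpGs. A green
end-to-end test therefore establishes that the algorithms recover planted
structure under realistic noise and boundedness — not that the pipeline is
robust to the confounders real 450K data carry.

`inject_perfect_marker()` overwrites one probe with disjoint class
supports (AB ≈ low ± 0.02, OM ≈ high ± 0.02), emulating the single fully
discriminating CpG the approach is designed to surface.

## Numerical and degenerate-input choices

* Beta values outside [0, 1] are rejected at construction, naming probe
  and sample; missing values are explicit `NA`s, pairwise-deleted per
  statistic, with per-probe minimums (`min_pairs = 3`).
* All rankings break ties deterministically by probe id, so reruns are
  byte-identical (verified in the suite).
* `m_transform()` clips to `[ε, 1−ε]` (default 1e−6) before the logit.
* Zero-variance inputs raise degenerate-input errors where a statistic is
  undefined (t test, Pearson) and degrade gracefully where a convention
  exists (all-zero Wilcoxon differences → p = 1; zero-variance probe in
  the cover graph → self-cover only).
* Round-trip I/O is lossless to 1e−12 (15 significant digits written).

## Validation scope

The quantitative acceptance suite
(`tests/testthat/test-acceptance.R`) checks: printed worked values of the
Δbeta arithmetic; the exact Wilcoxon floor (2·2⁻¹⁵ at n = 15; the filter
unattainable at n ≤ 10); brute-force oracle equivalence for maximal
cliques (200 random graphs ≤ 10 vertices) and minimum dominating sets
(200 instances ≤ 12 nodes at densities 0.1/0.3/0.6); end-to-end recovery
of a disjoint-support marker among 20,000 probes (rank 1 by merit,
survives domination, singleton panel separates completely, noise panels do
not); Bonferroni family-wise error control and the 0.001 false-pass rate
of the correlation screen under simulated nulls; and recovery of planted
deltas (±0.03 at n = 200) and trait correlation (±0.1 around r = 0.9).
Cohort-dependent headline counts from the motivating study are not
reproducible without its data and are deliberately out of scope, which is
why `scripts/acceptance.R` reports no numeric targets — it performs a
seeded smoke run and emits an empty target object.

## Known limitations

* The original toolchain's exact similarity metric, coverage criterion and
  threshold rule are not published; the choices here (mean absolute beta
  difference, |r| ≥ τ, labelled midpoint) are principled stand-ins and all
  config-exposed.
* Merit values are not comparable across cohorts of different size or
  noise; they rank sites within one analysis only.
* The exact dominating-set solver is bounded by `exact_limit`; above it
  the greedy solution may exceed the optimum (by at most the set-cover
  factor).
* Two-class designs only; the simulator's config accepts JSON, not YAML.
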