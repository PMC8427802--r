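---
title: "Methods: trajectory-based exosomal marker discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory-based exosomal marker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomarker)
```

## The analytical problem

Neuron-derived exosomes captured from serum carry a protein cargo whose
composition shifts as cognition declines from normal aging through mild
cognitive impairment (MCI) to Alzheimer's disease (AD). Given a log2
expression matrix of a few hundred exosomal proteins over a modest cohort
(five subjects per stage is typical for TMT discovery designs), the goal is
to find proteins whose expression moves *monotonically* across the three
stages — the candidates that could track progression rather than merely
separate endpoints — and to characterize them functionally, statistically
and structurally.

The pipeline is deliberately modular: every stage consumes and produces
plain tables, so each inference step can be audited or re-run in isolation.

## Stage profiles and standardization

Each protein is reduced to its ordered triple of per-stage mean log2
expression, (normal, MCI, AD). Because Euclidean distances on raw log2
triples are dominated by absolute abundance, each triple is centred and
scaled by its *population* SD (denominator n = 3). Constant triples carry
no trajectory information and cannot be scaled; they are excluded and
reported rather than silently kept. After standardization every retained
triple lies on the same unit-scale shape space, so clustering compares
trajectory shape only.

## Fuzzy c-means and the fuzzifier

Soft clustering is the right tool here: with three points per protein and
small n, many proteins sit between archetypes, and a hard partition would
hide that ambiguity. The package implements the standard fuzzy c-means
alternation (membership update, weighted centroid update) minimizing
$J=\sum_i\sum_k u_{ik}^m\lVert x_i-c_k\rVert^2$, with the membership rows
summing to one and $J$ non-increasing by construction (both properties are
asserted in the tests). Points coinciding with a centroid receive crisp
membership.

Two numerical choices matter:

* **Initialization.** Centroids start at c distinct data points chosen by a
  seeded draw. The draw happens in a canonical value-sorted row order, so
  the fit depends on the data and the seed, never on the row order of the
  input matrix.
* **Fuzzifier m.** The default is the feature-dimension heuristic
  $m = 1 + (1418/N + 22.05)D^{-2} + (12.33/N + 0.243)D^{-0.0406\ln N - 0.1134}$,
  which gives m ≈ 4.08 at N = 360 proteins, D = 3 stages. On standardized
  three-point profiles the archetypes are well separated, and recovery of
  planted structure is insensitive to m over the 2–4 range, so the
  heuristic default is safe; a numeric m can be supplied directly.

The cluster count defaults to c = 6 — the number of distinct trajectory
archetypes observed in three-stage cognitive-decline proteomes (one rising,
one falling, two concave, two convex) — and is exposed as a parameter. No
automatic model selection for c is attempted.

## Trajectory labels and bridge clusters

A centroid is classified from its step deltas Δ₁ = MCI − normal,
Δ₂ = AD − MCI with a tolerance ε (default 0.05 standardized units): both
deltas above ε is `monotone_up`, both below −ε `monotone_down`, opposite
signs give `valley`/`peak`, anything else `flat`. With only three support
points, a strict sign test would promote numerical noise into monotone
labels; ε suppresses that without masking real trends (a standardized
monotone centroid has |Δ| ≈ 1.22).

Bridge clusters are exactly the monotone-labelled clusters; bridge proteins
are the proteins hard-assigned (argmax membership, ties to the lowest
cluster index and reported) to them. A minimum-membership cutoff exists but
is off by default: the definition counts every cluster protein, and
membership filtering is better treated as a sensitivity analysis.

## Enrichment and co-pathway logic

Over-representation uses the exact hypergeometric upper tail with the
*identified proteome* (all proteins in the matrix) as background — the
defensible universe for proteomics, where the assay never sees most of the
genome. Benjamini–Hochberg adjustment is applied within each (cluster,
ontology) stratum, mirroring the per-ontology extraction of the five
smallest-q terms; a global-per-cluster mode is available. Terms smaller
than 3 or larger than 500 members in the background are skipped as
degenerate. Ties at the rank-5 boundary are broken by larger overlap k then
term id, deterministically.

The six per-cluster top-term lists (up to 5 × 4 ontologies = 20 terms each)
feed the co-regulation report: a term present in at least three lists is a
*core pathway*, in at least five a *pivotal pathway*, and the full exclusive
intersection profile (upset counts) is emitted so the partition of the term
union can be checked exactly.

## Differential expression and key proteins

The fold change is computed directly on the stored log2 values as a
difference of arithmetic means, which equals the log2 ratio of geometric
means on the original scale — the package asserts this equivalence to
1e−12 in its tests. The default test is Student's pooled-variance t
(Welch by flag); p-values are left unadjusted because the DEP criterion is
a raw p < 0.05 together with |log2FC| ≥ 0.5, and the fold-change gate, not
the p-gate, is what controls spurious calls at this sample size when noise
is moderate. With noisier data (log2 SD ≈ 0.5 at n = 5) the fold-change
threshold sits only ~1.6 null SEs out and the joint null call rate rises
toward the p-gate level of 5%; the tests encode both regimes. An optional
BH mode gates on q instead.

Key proteins are the per-(bridge cluster × comparison) intersections of
bridge proteins with DEPs, with empty intersections retained explicitly.
Direction concordance between a key protein's fold change and its cluster's
trend is reported but not used as a filter.

## Network topology

The interaction graph is built from a STRING-style edge list (scores either
integers 0–999 or floats 0–1, auto-detected and never mixed; default gate
400, medium confidence), collapsed to a simple undirected graph and
restricted to bridge proteins. Scores gate edge existence only: path
lengths are hop counts, and betweenness is the unnormalized
shortest-path-pair accumulation (a normalized column is provided
alongside). All shortest paths between key-protein pairs are reported
descriptively — a connecting cascade is a hypothesis generator, not a
tested statistic.

## ELISA calibration

Standard curves use the four-parameter logistic
$OD(x)=d+(a-d)/(1+(x/c_0)^b)$, the immunoassay standard, fitted by
Levenberg–Marquardt least squares from the prescribed initialization
(a = min OD, d = max OD, c₀ = median positive concentration, b = 1) with an
RSS tolerance of 1e−10; the zero-concentration standard is the lower
asymptote limit. Inversion is closed-form, restricted to the open interval
between the fitted asymptotes, with explicit out-of-range results. Marker
concentrations are normalized per sample to CD81 (ratios undefined at
non-positive CD81 are flagged out), and stage comparisons use pairwise
t-tests annotated with stars (* < 0.05, ** < 0.01, *** < 0.001,
**** < 0.0001; the three-star tier is interpolated for completeness).

A known limitation, documented deliberately: on standard series whose top
point rises far above an otherwise shallow run (e.g. a seven-point kit
series ending 0.517 → 1.524 OD between 2.5 and 5 ng/ml), the least-squares
4PL surface has no interior sigmoid optimum — the fit degenerates toward a
power curve with an unbounded upper asymptote, and inverse predictions in
the low-OD region land well above what a locally interpolating model (or
flanking-standard interpolation) would give. The package reports exactly
what the 4PL least-squares fit implies rather than silently switching
models; users who need local agreement on such series should inspect the
fitted asymptotes and residuals, which the `standard_curve` object exposes.

## The synthetic cohort generator

The generator is first-class, tested code that defines the study conditions
the pipeline is validated under:

* 360 proteins over six trajectory archetypes: 60 `monotone_up`, 60
  `monotone_down`, 120 `valley`, 120 `peak` (two concave and two convex
  clusters being what three-stage decline proteomes show; no flat cluster
  is planted by default, though the shape is available).
* 5/5/5 samples per stage; offsets symmetric around MCI:
  (−δ, 0, +δ), (+δ, 0, −δ), (0, −δ, 0), (0, +δ, 0), (0, 0, 0).
* Per-protein baselines uniform on [20, 30] log2 units (typical reporter
  intensity scale) — irrelevant after standardization, realistic before.
* Gaussian log2 noise, default SD 0.5 (a free choice: discovery data
  publish no variance estimates); recovery experiments use δ = 1.5,
  SD = 0.3, a strong-but-plausible effect at which planted monotone
  proteins should be recovered with ≥ 95% sensitivity and ≥ 90% precision.
* Annotation sets with one planted term per monotone shape at 80% purity
  (partial overlap exercises the hypergeometric counting), plus uniform
  background sets tagged BP/CC/MF/KEGG.
* An interaction list whose planted 4-node path (one rising endpoint, two
  falling interior nodes, one falling endpoint) carries the maximal score;
  noise edges connect only non-path nodes, so the planted path is the
  unique shortest route by construction.
* 4PL plates generated at the printed kit concentrations
  (0–5 ng/ml, two-fold steps).

What the generator does *not* emulate — missing-value structure beyond a
simple missing-at-random option, TMT channel interference, batch effects,
isolation-efficiency artifacts — bounds what passing tests show: they
validate the inference machinery under its own assumptions, not robustness
to real-world artifacts.

## Problem sizes and determinism

All simulations in the test suite run at the study scale (360 × 15) or
below; the heaviest checks are 10-seed recovery experiments and a 100-graph
brute-force betweenness comparison on ≤ 8 nodes, keeping the whole suite in
the order of a minute. Every stochastic stage takes an explicit seed; the
pipeline derives per-stage seeds from one global seed by hashing stage
names, and identical configurations reproduce byte-identical output tables.
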