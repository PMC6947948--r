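---
title: "Cross-role triplet dysregulation: model, choices and limitations"
author: "TripletNet maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-role triplet dysregulation: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TripletNet)
```

## The model

A *cross-role triplet* is a triangle in a protein–protein interaction
(PPI) graph whose three distinct genes are assigned the three
complementary roles immune, inflammation and disease, each gene's role
licensed by a curated role catalog. The triangle requirement is
deliberate: the dysregulation score consumes correlation changes for all
three gene pairs, so all three interactions must exist. A gene with
several catalog roles may appear in different triplets under different
roles, and one triangle of multifunctional genes can yield up to six
role assignments; each valid assignment is scored as its own triplet
(a first-assignment-only mode is available), because the scoring
equations need a fixed role per gene and no principled selection rule
exists among valid assignments. Within one triplet a gene can never
occupy two role slots, since the three genes of a triangle are distinct
by construction.

Dysregulation between cases and controls is measured on two axes:

* **Score_dif** — the product of the three per-gene two-sided t-test
  p-values (pooled-variance Student's test by default; Welch behind the
  `test` flag). It lives in (0, 1]; small values indicate coordinated
  differential expression. P-values are floored at 1e-300 so the product
  never underflows to exact zero.
* **Score_PCC** — the absolute product of the three between-group
  Pearson-correlation differences, in [0, 8]; large values indicate
  rewiring of the triangle's co-expression structure.

The axes are combined by equally weighted ranks: Score_dif is ranked
descending in dysregulation (smallest product → largest rank value),
Score_PCC ascending (largest change → largest rank value), ties receive
average ranks, and the final ranking score is the mean of the two ranks.
This orientation is the only one under which a higher final ranking
score always means stronger dysregulation.

## Permutation significance

Case/control labels are shuffled with group sizes preserved; all
triplets are rescored per permutation; and each triplet receives the
add-one empirical p-value `(1 + #{permuted final score ≥ observed}) /
(1 + n_perm)`, which is never zero and is bit-reproducible under a fixed
seed. The comparison is per triplet (not pooled across triplets), and
the ≥ convention plus the add-one correction are declared choices rather
than something the score itself implies.

Turning a permutation's score pair into a *final ranking score* needs a
ranking frame, and the choice matters. Re-ranking each permuted cohort
jointly ("co-permuted" frame) looks natural but has a structural flaw
for recovery studies: shuffling removes the signal from every triplet at
once, so the permuted ranks are close to exchangeable across the cohort,
and a triplet's attainable p-value is bounded near its observed
normalized rank — when a fifth of the cohort is truly dysregulated, most
truly dysregulated triplets can never reach p < 0.05 no matter how
strong their signal. We measured exactly this saturation (recovery
capped near 50% in the standard planted scenario). The default therefore
ranks each permuted score pair against the *observed* cohort's score
distributions: this asks how extreme the triplet's final ranking score
would look under random labels while the ranking frame is held fixed, is
calibrated under the complete null (false-positive rate inside the exact
binomial 99% interval around the nominal 5%), and retains power when
much of the cohort carries signal. The co-permuted variant remains
available via `rankFrame = "permuted"`.

Triplets with `permP < alpha` (strict inequality, default 0.05, no
multiplicity correction) constitute the dysregulated subnetwork.

## Core clusters and sample classification

Core clusters are extracted from the dysregulated network by greedy
cohesiveness optimisation in the style of ClusterONE. Cohesiveness of a
node set V is `w_in / (w_in + w_bound + p·|V|)` with unit edge weights
and per-node penalty p (default 2, modelling unobserved interactions).
Candidates grow from uncovered seeds in decreasing-degree order by
single-vertex additions and removals; sideways (equal-value) moves to
unvisited states are allowed so plateaus can be crossed, and the best
state seen along a trajectory is kept. Connected components are added as
natural zero-boundary candidates, since a fitness valley can separate
them from every seed trajectory. Candidate pairs with overlap score
`|A∩B|²/(|A||B|) ≥ 0.8` are merged; clusters below 3 members or induced
edge density 0.5 are dropped; the top 4 by cohesiveness are reported
(all thresholds configurable; the defaults mirror the published
ClusterONE defaults).

Whether a core cluster separates cases from controls is assessed by
subsampled k-means consensus clustering of the samples restricted to the
cluster's genes: for each k in 2..kMax, 100 resamples of 80% of samples
are clustered by k-means (Euclidean distance on sample profiles, 10
restarts, a fixed RNG stream per (k, resample) so disabling one k does
not perturb another), and the consensus matrix records the co-clustered
fraction among co-sampled pairs. Model selection follows the area under
the empirical CDF of consensus values (trapezoidal rule over [0, 1],
with tiny sampling-noise non-monotonicities clamped): the delta-area at
k is the relative increase over k−1 (at k = 2, the area itself), and the
chosen k is the largest k whose delta-area still reaches the elbow
threshold (default 0.1) — the last k before the CDF area stops growing
appreciably, a quantitative version of the usual "smallest increase"
reading of the delta-area plot. The final assignment cuts average-
linkage hierarchical clustering of 1 − consensus at the chosen k, and a
Pearson chi-square test without continuity correction (groups with zero
samples dropped) quantifies the association between consensus groups
and disease status. Identical samples make the consensus degenerate;
the report then carries an instability flag instead of pretending the
grouping is meaningful.

## Drug overlay

Drug–target records are joined onto the dysregulated gene network by
bare symbol match (no action or affinity filtering, no approval-status
filter): each drug that targets at least one dysregulated gene becomes a
node connected to its present targets, drugs are ranked by degree (ties
broken lexicographically by drug id), and per-drug subnetworks induce
the drug, its targets and the gene–gene edges among them.

## The synthetic generator

`simulateScenario()` emulates the statistical structure the scoring
method assumes: role-labelled genes; a PPI graph that is the union of
planted cross-role triangles (one gene per role, disjoint gene sets)
and an Erdős–Rényi background; and a two-group expression matrix in
which each triangle's gene trio is drawn from a group-specific
trivariate normal. Null triplets use the same mean and the same
compound-symmetric correlation (rho_ctrl) in both groups; planted
triplets shift the case-group means by `effectMeanShift` standard
deviations and switch the case-group correlation to rho_case. A
compound-symmetric correlation of −0.6 on three genes is not positive
definite (its smallest eigenvalue is 1 + 2ρ < 0), so requested matrices
are repaired to the nearest positive-definite correlation matrix;
realised control-group correlations under rho_ctrl = −0.6 are therefore
about −0.5, which slightly shrinks the planted correlation flip relative
to its nominal value. A configurable fraction (default 0.15) of
role-carrying background genes receives a second role to exercise the
multi-assignment enumeration; triangle genes keep single roles so the
planted truth stays a one-to-one map from triangle to triplet.

Default study conditions are 30 planted and 120 null triplets, 20 cases
and 20 controls, mean shift 1.5 SD and correlation flip −0.6 → +0.6 —
a deliberately favourable desk-scale regime for measuring recovery; the
matched no-signal scenario (0 planted, 150 null) measures calibration.
What passing these tests shows is that the scoring machinery recovers
exactly the kind of signal it models, at calibrated error rates. What
it does not show: robustness to microarray-specific artefacts (probe
effects, batch structure, heavy-tailed noise), to unbalanced or tiny
groups, or to signal shapes other than mean shift plus correlation
flip — none of which the generator emulates.

## Numerical and degenerate-input choices

* Symbols are uppercased and whitespace-stripped everywhere; no alias
  resolution. Expression values are used exactly as provided (no log
  transform or normalisation) — whether to pre-transform is the user's
  call, via the input files.
* Zero pooled variance in a t-test: p = 1 for equal means, the 1e-300
  floor for unequal means. Constant expression vectors correlate as 0
  with a warning. Genes with missing values, or triplets whose genes are
  absent from the expression data, are dropped from scoring with a
  message.
* Rank ties always use average (fractional) ranks — deterministic and
  input-order-free. Triplet output order is lexicographic by (immune,
  inflammation, disease); cluster and drug ties break lexicographically.
* A single global seed fans out to per-stage substreams (a fixed affine
  map into the 32-bit integer range), so toggling one pipeline stage
  never changes another stage's randomness, and two runs with the same
  config and seed are byte-identical.

## Problem sizes

The bundled scenarios are sized for quick, repeatable runs on one core:
the recovery and calibration scenarios use 150 triplets over ~470 genes
with 40 samples and 200 permutations (a few seconds each with the
vectorised scorer); the oracle-equivalence checks run the brute-force
triangle enumerator on graphs up to 50 nodes and the exhaustive-subset
cohesiveness oracle up to 8 nodes. Users analysing real cohorts should
raise `nPerm` to the customary 1000.

## Known limitations

* Triangle enumeration is exact, so a gene catalog and PPI graph that
  produce very many triangles (dense hub neighbourhoods) will produce a
  correspondingly large scored cohort; there is no sampling shortcut.
* The greedy cohesiveness search matches exhaustive optima on small
  graphs but carries no global guarantee at scale — the same trade-off
  the original plugin makes.
* The chi-square association is unreliable for very small expected cell
  counts; the test warns through `stats::chisq.test` semantics
  (suppressed, as counts this small already mean the classification is
  not trustworthy).
* Consensus-clustering model selection with the delta-area rule is a
  heuristic; the full report (per-k consensus matrices, CDF areas,
  delta-areas) is exposed so the choice can be inspected rather than
  trusted blindly.
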