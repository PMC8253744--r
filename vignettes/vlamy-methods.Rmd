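---
title: "Predicting light-chain amyloidogenicity from region-aware sequence features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting light-chain amyloidogenicity from region-aware sequence features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In AL (light-chain) amyloidosis, the variable domain of an antibody light
chain (V~L~, roughly 105–115 residues) misfolds and aggregates into amyloid
fibrils. Whether a given V~L~ sequence is amyloidogenic is hard to call from
generic aggregation predictors, because all light chains share one
architecture: four conserved framework regions (FR1–FR4) scaffolding three
hypervariable loops (CDR1–CDR3). That common architecture is also an
opportunity — the same physicochemical property can mean different things in
a solvent-exposed CDR loop than in the buried framework, so features become
informative once they are computed *per region* rather than over the whole
chain.

`vlamy` implements this region-aware approach end to end: segmented sequence
I/O, per-region physicochemical features, an interpretable rule-list
classifier with an imbalance-aware decision threshold, evaluation protocols,
alignment conservation profiling, gatekeeper analysis around
aggregation-prone regions (APRs), and a synthetic-data generator that makes
the whole pipeline testable without any external resource.

## Inputs and segmentation

Records enter as unaligned FASTA plus a region-annotation table giving
1-based, inclusive start/end positions for FR1, CDR1, FR2, CDR2, FR3, CDR3
and FR4 (the IMGT-style segmentation that curated light-chain databases
export). The package consumes these boundaries; it never computes them —
antibody numbering software is a separate concern. Validation enforces that
the seven regions tile the sequence exactly, in order, with no gaps or
overlaps; records failing this (or containing nonstandard residues, under
the default `strict` policy) are excluded and reported, which mirrors how
curated datasets of this kind are filtered before analysis. The alternative
`mask` policy keeps such records and simply omits the offending positions
from every average and fraction.

## The feature model

Each feature is a mean property over a region,
$F_{avg} = \frac{1}{N}\sum_{i=1}^{N} F_i$, or a category fraction
(count/length). The seven-feature panel used by the default model:

| feature | region | property |
|---|---|---|
| `f_hyd_cdr` | pooled CDRs | consensus normalized hydrophobicity (Eisenberg; AAIndex EISD840101) |
| `f_gk_fr` | pooled FRs | gatekeeper fraction (D, E, R, K, P) |
| `f_dis_vl` | whole V~L~ | mean per-residue disorder score |
| `f_beta_vl` | whole V~L~ | Chou–Fasman β-sheet propensity (CHOP780202) |
| `f_np_vl` | whole V~L~ | non-polar fraction (A, G, I, L, M, P, V) |
| `f_ct_cdr` | pooled CDRs | charge-transfer capability (CHAM830107) |
| `f_tfe_fr` | pooled FRs | transfer free energy to surface (BULH740101) |

The rationale: exposed hydrophobic CDR surface seeds aggregation
(`f_hyd_cdr` up in amyloidogenic chains); charged and β-breaking
"gatekeeper" residues in the frameworks flanking the CDRs suppress it
(`f_gk_fr` down); disorder-prone, β-prone and non-polar composition raise
intrinsic aggregation propensity. Gatekeeper content is stored as a fraction
and rendered as a percentage in reports.

Two definitional choices deserve explanation:

* **CDR pooling.** "Hydrophobicity of the CDRs" is computed by concatenating
  all CDR residues before averaging, i.e. length-weighted. Averaging the
  three per-CDR means instead would up-weight the three-residue CDR2
  enormously. Pooling is the default; `cdr_pooling = "mean_of_means"` is
  available for sensitivity analysis.
* **CHAM830107.** The published AAIndex entry assigns the "capable" level to
  N, D, E and G. This differs from the chemically motivated set of
  charge-transfer *acceptor* side chains (D, E, N, Q) that the feature is
  usually described with; the package bundles the scale exactly as published
  (verified against `seqinr::aaindex` by unit test) and exposes the
  {D, E, N, Q} set separately as the `charge_transfer_acceptor` residue
  category.

Bundled scales are data fixtures transcribed from their published sources;
`read_aaindex()` reads any AAIndex1 flat file for the extended panel, which
adds every registered scale × {V~L~, CDRs, FRs}, every category fraction over
the same regions, and the global descriptors symmetric charge
($({n_+-n_-})^2/L^2$ over K/R vs D/E — a local convention, isolated in one
function because no published formula exists), aromaticity and β-propensity.

### Disorder

The upstream method obtained per-residue disorder from the IUPred2A server.
A web service cannot be a build dependency, so `vlamy` ships a pluggable
provider: the default computes a sliding-window mean (window 11, truncated
at the termini) of the TOP-IDP disorder-propensity scale; externally
computed profiles (including IUPred2A exports) can be supplied as a TSV of
`id`, `position`, `score` and take precedence when given. This is
deliberately *not* an IUPred2A reimplementation — reproducing its
pairwise-energy estimation is out of scope, and analyses that depend on its
exact values should import them. One consequence worth knowing: with a
window wider than 1, `f_dis_vl` is not purely compositional (terminal
truncation gives end residues slightly different weight), so
order-invariance holds exactly for the other six features and for
`f_dis_vl` only at `window = 1`.

## The classifier

The model is an ordered rule list learned by separate-and-conquer, in the
style of the PART algorithm: grow an unpruned partial C4.5-style decision
tree on the not-yet-covered instances, extract the leaf covering the most
instances as the next rule, discard the instances it covers, repeat. The
loop ends when the partial tree collapses to a single leaf, whose class
counts become the default for instances matching no rule. Rules keep their
leaf counts, so prediction yields a class probability — the Laplace-smoothed
positive fraction $(n_{pos}+1)/(n_{covered}+2)$ of the first matching rule —
rather than a bare call. The result is as interpretable as the tree family
it comes from: `tidy()` on a fitted model prints the ordered rules with
their coverage and probabilities.

Split search follows the C4.5 conventions for numeric attributes: candidate
thresholds are midpoints between consecutive distinct sorted values;
candidates whose information gain falls below the feature's average
candidate gain are screened out; the surviving candidate with the highest
gain ratio wins, with ties broken toward the lower feature index and then
the lower threshold. Design choices where the classic algorithm leaves room:

* **Minimum node size, not minimum branch size.** `min_leaf` (default 2) is
  the smallest node that will still be split, and a candidate cut needs only
  one instance per side. Together with a guaranteed-progress fallback — when
  no candidate has positive gain (an exact-XOR node), the most balanced
  admissible cut is taken — this makes training on conflict-free data
  (no duplicated feature vector with discordant labels) reproduce the
  training labels exactly, a property the test suite asserts on random
  datasets.
* **No pruning.** The unpruned variant is the intended configuration;
  `unpruned = FALSE` is refused rather than silently approximated.
* **Numerics.** When two adjacent representable feature values are so close
  that their midpoint rounds up to the larger one, the threshold falls back
  to the smaller value so the cut genuinely separates them. Entropies are
  computed from integer class counts via a cached $k\log_2 k$ table.
  Tree growth and the separate-and-conquer loop are compiled (Rcpp) with
  presorted, stably-partitioned per-feature index lists — the layout used
  by CART-family implementations — because unpruned trees on noisy data
  degenerate to depth ~n/2 and would otherwise dominate cross-validation
  time.
* **Determinism.** Training has no stochastic step; the seed argument is
  recorded in the model metadata for provenance. Identical data give
  byte-identical serialized models (JSON at 17 significant digits, which
  round-trips doubles exactly).

### The decision threshold

The reference dataset for this problem is ~19% positive, and a
probability-0.5 cut on an imbalanced rule list buys specificity with
sensitivity. The default operating point is therefore P(amyloid) ≥ 0.15,
with ties classified positive. `select_threshold()` also offers data-driven
sweeps (maximum balanced accuracy or Youden's J over all distinct predicted
probabilities, ties toward the smaller threshold, favoring sensitivity).
One interaction to be aware of on very small datasets: Laplace smoothing
keeps the probability of a pure-negative leaf at $1/(n+2)$, which exceeds
0.15 for leaves of five or fewer instances — so consistency checks
(resubstitution, leave-one-out on a handful of points) are evaluated at the
majority threshold 0.5, while 0.15 remains the operating default for
realistically sized data.

## Evaluation

`confusion_counts()` / `confusion_metrics()` implement accuracy
$(TP+TN)/(TP+TN+FP+FN)$, sensitivity $TP/(TP+FN)$ and specificity
$TN/(TN+FP)$ with the amyloid class positive; degenerate denominators give
`NA` with a warning, never a silent zero. ROC curves sweep every distinct
score as a threshold, and the trapezoidal AUC equals the pairwise
probability $P(s_{pos}>s_{neg})+\tfrac12 P(tie)$ — asserted against a
brute-force pairwise oracle and against pROC in the tests. Because of the
class imbalance, AUC is the headline metric; threshold-dependent metrics are
reported alongside.

`vl_cross_validate()` retrains the full model per split under four
protocols: resubstitution (`self`), leave-one-out, stratified k-fold
(pooled predictions), and repeated stratified 90/10 subsampling without
replacement within each class, aggregated as mean ± sd over iterations.
Stratification is applied to k-fold as well as resampling, and the fixed
0.15 threshold is applied to every split (per-split re-optimization is
available through `select_threshold()` but off by default).
`vl_feature_ablation()` re-runs a protocol with each feature removed and
with each feature alone.

## Conservation profiling

Given an externally computed multiple sequence alignment, `profile_msa()`
reports per column and per group: Shannon entropy
$H=-\sum_a p_a\log_2 p_a$ over the 20 residues with gaps excluded from the
distribution, occupancy (fraction non-gap) as the separate gap channel, and
the consensus residue (modal non-gap residue, ties alphabetical). Treating
gaps via occupancy rather than as a 21st symbol keeps entropy a pure
substitution signal; the logarithm base is configurable (bits by default).
Lower entropy means stronger conservation. Alignment construction itself is
out of scope — the profiler consumes any aligned FASTA.

## APR flank analysis

APR intervals from any external predictor (TANGO- or WALTZ-style exports)
are consumed as a 1-based inclusive TSV. For each APR,
`flank_gatekeepers()` counts gatekeepers in the ±k flanks (default k = 3),
truncating flanks at the sequence boundaries rather than discarding
terminal APRs; an APR is *protected* when at least one gatekeeper occurs in
either flank. `apr_region_map()` assigns each APR to the FR/CDR regions it
overlaps with per-region residue counts (overlaps sum exactly to the APR
length), and `apr_summary()` aggregates per-region APR counts and the
unprotected fraction — the quantity that separates amyloidogenic from
non-amyloidogenic datasets in this kind of analysis.

## The synthetic-data generator

`simulate_vl()` emits κ/λ-like segmented records with planted class
effects, so every module (and the full pipeline) is testable offline.
Region lengths are drawn per sequence from IMGT-like ranges (FR1 23–26,
CDR1 5–12, FR2 17, CDR2 3, FR3 36–39, CDR3 8–13, FR4 10–11). Residues are
drawn i.i.d. per position from region-specific categorical distributions:
uniform over the 20 residues in CDRs; in FRs the five gatekeepers carry
0.25 total mass so depletion has headroom. These are documented simulation
constants, not biological claims — the generator makes no attempt to mimic
germline sequences, somatic hypermutation or real database composition, so
passing end-to-end tests demonstrates that the pipeline recovers planted
signal, not that it matches any particular biological dataset.

Positive-class effects are planted by exponential tilting, which acts
directly on the quantities the features measure:

* `delta_hyd` — CDR residue weights multiplied by
  $e^{\delta\,\mathrm{HNC}(a)}$ (more hydrophobic CDRs);
* `delta_dis` — all weights multiplied by $e^{\delta\,\mathrm{TOPIDP}(a)}$
  (more disorder-prone chains);
* `delta_gk` — the gatekeepers' *share* of FR mass is set to
  $0.25\,(1-\delta_{gk})$ after the other tilts.

The share formulation for `delta_gk` matters: a naive per-residue
multiplicative depletion is silently overwhelmed by the disorder tilt
(TOP-IDP is high for P, E and K — all gatekeepers), which would move
gatekeeper content in the *wrong* direction at the default settings. Acting
on the share guarantees the planted direction, reduces to the naive
definition when `delta_dis = 0`, and is a no-op when all deltas are zero —
in which case the two classes are drawn from identical distributions
(exchangeable null). Defaults are `delta_hyd = delta_dis = 1.5`,
`delta_gk = 0.5`: strong, unambiguously recoverable effects. Isotype labels
are metadata only (75% of positives λ, negatives split evenly), for
exercising group-wise reporting. `simulate_vl_imbalanced()` reproduces a
stated class mix (default 19% positive, rounding to nearest).

## Problem sizes and what the checks show

The package's own acceptance checks (`tests/testthat/test-acceptance.R`,
recomputed from scratch by `scripts/acceptance.R`) run at these sizes,
chosen to give stable statistics at interactive runtimes: exact metric and
entropy identities on hundreds of randomized cases; rule-learner consistency
on random conflict-free datasets up to n = 200 with 2–7 features, with the
root split cross-checked against exhaustive gain-ratio search at n ≤ 20;
end-to-end recovery on 300+300 simulated sequences — leave-one-out AUC
≥ 0.9 under the default planted effects and within [0.40, 0.60] under the
all-zero null; feature-direction sign agreement over five seeds at 100+100;
and byte-level determinism of datasets, models and reports under fixed
seeds. Resampling summaries in the acceptance script use 100 iterations;
the protocol itself supports the full 5000.

## Known limitations

* Region boundaries are trusted input; there is no numbering engine, and
  records with inconsistent annotations are dropped rather than repaired.
* The builtin disorder provider is a propensity smoother, not IUPred2A;
  absolute disorder values (and any model trained on them) shift when a
  different provider is imported.
* The rule learner is of the PART family but is not a bit-for-bit Weka
  clone; rule lists learned from identical data by other implementations
  may differ in tie cases.
* The 0.15 operating threshold is a property of the ~1:4 imbalance regime
  it was tuned for; datasets with different prevalence should re-run
  `select_threshold()`.
* APR analysis consumes predictor output; it does not score aggregation
  propensity itself.
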