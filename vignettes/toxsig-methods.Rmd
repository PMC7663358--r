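---
title: "Methods: network-based toxicant signature analysis in toxsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based toxicant signature analysis in toxsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxsig)
```

`toxsig` implements a pipeline for finding metabolic signatures common to
different hepatotoxicant exposures: differential statistics on plasma
metabolite tables, concordance analysis of fold-change profiles across
exposures, gene-set activation scoring with permutation nulls, and
network-based prediction of plasma metabolite changes from liver gene
expression. This vignette is the package's own account of the underlying
models, the tunable parameters, the numerical choices, and what the bundled
synthetic benchmark does and does not demonstrate.

## Differential statistics

Raw abundance tables (features × samples, a control and a treated group)
are preprocessed in two steps: missing entries of a feature are replaced by
that feature's minimum observed value — a conservative stand-in for
measurements below the detection limit, which is the dominant missingness
mechanism in untargeted profiling — and the table is log-transformed.
Metabolite fold changes are kept on the natural-log scale; gene fold
changes on the log₂ scale, the convention expected by the network scoring
step. Both are recorded in the result metadata.

Per feature, `welch_test()` computes the unequal-variance *t* statistic
with Welch–Satterthwaite degrees of freedom and a two-sided p-value
(two-sided because untargeted profiling has no a-priori direction).
`bh_fdr()` applies Benjamini–Hochberg step-up adjustment; the pipeline's
default significance screen is q < 0.1, and the p < 0.05 column is
available for users who prefer the unadjusted criterion. The degenerate
zero-variance-in-both-groups case returns t = 0, p = 1 when the means
agree, rather than an undefined statistic.

## Concordance across exposures

Pairs of exposure conditions are compared by the Pearson correlation of
their log fold-change profiles over shared features — over all common
features, or over the features significant in *both* conditions
(`mode = "significant"`), which sharpens the comparison to the responsive
part of the profile. Conditions are clustered by `hclust` with distance
1 − r and average linkage. The method choice is deliberate: the
correlation-based distance matches the correlation-centric comparison the
rest of the analysis uses, and average linkage avoids the chaining of
single linkage on small condition sets. A reported correlation requires at
least 3 shared features; fewer is an error naming the pair.

## Gene-set activation: AFC and AAFC

For a gene set with measured members g ∈ S and log fold changes f(g):

* **AFC** (aggregated fold change) = Σ f(g) — signed; the sign is the
  direction of pathway regulation.
* **AAFC** (absolute aggregated fold change) = Σ |f(g)| — magnitude only;
  suited to injury modules whose member genes respond in mixed directions.

Significance is assessed against size-matched random gene sets drawn
*without replacement* from the observed fold-change pool (a
with-replacement flag exists for sensitivity analysis). With n_draws random
scores R:

* p = (1 + #{R ≥ actual}) / (n_draws + 1) — upper tail, ties counted as
  extreme, add-one smoothing so p is never exactly 0. Ties must count
  because a discrete null (small pools) otherwise yields anti-conservative
  p-values.
* z = (actual − mean(R)) / sd(R); a degenerate null (sd = 0) yields z = 0
  when the actual score equals the null mean and a signed infinity flag
  otherwise.

Module activation (`activate_modules()`) first restricts the gene universe
to significantly changed genes (q < 0.1) and builds the pool from that
filtered table: the question it answers is whether a module is
over-represented *among the responding genes*, not whether the genome
responded. An all-genes pool is available through `score_gene_sets()` for
sensitivity analysis. Sets with no member in the universe are reported with
a `null_result` flag rather than dropped, so downstream tables stay
complete. Default n_draws is 10,000; a seed is mandatory and echoed in
every output row.

## TIMBR production scoring

The transcriptionally inferred metabolic biomarker response (TIMBR)
approach asks, for each extracellular metabolite: did the treated
transcriptome make the network's production of this metabolite cheaper or
more expensive? The ingredients:

**Reaction fold changes.** Each reaction's GPR rule is evaluated over the
gene log₂ fold changes with AND = min (an enzyme complex is limited by its
scarcest subunit) and OR = max (isozymes substitute for each other).
Unmeasured genes contribute 0 — no measured change is treated as no change
— and reactions without a GPR get 0.

**Condition weights.** With c the reaction fold change clipped to
[−L, L] (L = 4 by default, so a single extreme gene cannot dominate the
objective): treated weight 2^(−c/2), control weight 2^(+c/2). The
symmetric form makes fc = 0 exactly neutral (both weights 1) and makes the
two conditions mirror images.

One subtlety: min/max aggregation is not an odd function
(min(−x) = −max(x)), so evaluating a single reaction fold change and
negating it for the control side would break the mirror symmetry for
AND/OR rules. `production_scores()` therefore evaluates each condition from
its own perspective — treated weights from eval(f), control weights from
−eval(−f). For single-gene rules this reduces to the plain formula above,
and it guarantees exact antisymmetry: negating every gene fold change swaps
D_control and D_treatment and negates every raw score, a property the test
suite checks on random inputs.

**Demand LPs.** For metabolite m, an irreversible demand reaction
(consuming one unit of m, bounds [0, ∞)) is added, and

* v_max = max demand flux subject to S v = 0 and the reaction bounds;
* D_cond = min Σ w_r |v_r| subject to S v = 0, bounds, and demand ≥ f·v_max.

The fraction f defaults to 0.9: at f = 1 the flux pattern is pinned to the
capacity vertex and weight differences cannot re-route flux, while a
strict-interior fraction keeps the network near capacity yet leaves the
routing freedom that the weights are meant to probe. f is a config knob
(`timbr_config(fraction = ...)`).

**Scores and classes.** raw = log₂(D_control / D_treatment), positive when
treatment makes production cheaper (predicted plasma increase). Because
only relative magnitudes are comparable across metabolites, scores are by
default standardized across all feasible metabolites (z-score); both raw
and standardized values are emitted. Classification uses strict cut-offs:
score > 0.1 increased, score < −0.1 decreased, otherwise unchanged — a tie
at exactly ±0.1 classifies as unchanged. Metabolites with v_max = 0 are
reported `feasible = FALSE` and carry no class.

**Evaluation.** Over observed-significant metabolites that are feasibly
scored, a prediction counts as correct only when the class sign matches
the observed fold-change sign; "unchanged" never counts as correct, so the
reported fraction is conservative and the per-metabolite breakdown is
attached for users who want to score "unchanged" differently. The
shuffled-gene control (`randomized_control()`) permutes the gene-to-value
assignment, reruns everything, and reports the same statistic: the gap
between real and shuffled accuracy is the information content of the
actual expression pattern.

## MFA flux constraints

In vivo flux estimates are conventionally reported relative to a reference
reaction fixed at 100 (citrate synthase in hepatic studies).
`relative_to_absolute()` rescales them through one anchor reaction with a
known absolute flux (e.g. derived from a tracer infusion rate and body
weight); the anchor is an explicit required input rather than a guess.
Each converted estimate v ± sd becomes the LP bound interval
(v − k·sd, v + k·sd), with k = 2 by default — roughly a 95% interval under
normal errors — clipped to the reaction's structural range, so a
measurement can restrict but never widen the network, and the lower bound
of an irreversible reaction never goes negative. A measurement whose lower
bound exceeds the structural upper bound contradicts the network and is an
error, not a silent clamp. Literature uptake/secretion rates use the
standard sign convention: uptake is negative exchange flux, giving bounds
(−rate, 0); secretion gives (0, rate). `apply_constraints()` keeps the
replaced bounds so `remove_constraints()` restores the network exactly.

## The LP solver

The demand problems are dense, modestly sized (tens to a few hundred
variables) bounded-variable LPs. The package ships a two-phase primal
simplex with upper/lower bounded variables: Dantzig pricing with a switch
to Bland's rule after a run of degenerate pivots (anti-cycling), reduced
cost tolerance 1e-9, and infinite bounds encoded as a ±1e6 sentinel so
programs are never unbounded (file I/O preserves true infinities as
"inf" tokens). Reversible reactions are split into non-negative
forward/backward components so the absolute-value objective is linear.
Alternate optima are acceptable by construction: only the objective value D
enters the score, never the flux pattern. The solver is validated in the
test suite against a brute-force enumerator of basic feasible solutions on
random networks; during development it was additionally cross-checked
against an independent HiGHS implementation on 120 random programs with
exact agreement.

## The synthetic benchmark

`synthetic_scenario()` describes a two-group acute-exposure study shaped
like the motivating experimental designs: 8 samples per group, hundreds of
genes, tens of plasma metabolites, and flux estimates anchored at 100 with
5–15% relative standard deviations. The default toy network has 12 linear
pathways of 5 reactions from a shared uptake to distinct extracellular
products; every reaction carries a GPR over fresh genes (singles, AND
pairs, OR groups), each pathway has one parallel alternative route so
weight changes can actually re-route flux, and each product has a secretion
exchange so constrained flux always has an exit. The default perturbation
design shifts the genes of 4 pathways (two up, two down) by δ = 2 on the
log scale against noise σ = 0.25, and imposes the matching shift on each
perturbed pathway's terminal metabolite; 5% of cells go missing completely
at random. Those defaults are the benchmark condition used by the
acceptance checks; δ/σ/n were chosen once as a strong-but-noisy regime a
well-powered designed study would target.

Two deliberate simplifications: metabolite effects are *imposed*, not
simulated through kinetics — the claim under test is that the pipeline
recovers designed directions, not that it simulates mechanism — and
missingness is completely at random, which is exactly the assumption the
minimum-value imputation rule needs and no more. Consequently, passing the
benchmark demonstrates correct statistics, scoring and plumbing on data
with known truth; it does not demonstrate robustness to informative
missingness, batch effects, kinetic feedback, or the scale of a real
genome-scale reconstruction.

## Problem sizes and determinism

The test suite runs the oracle comparison on 100 random networks of at
most 8 reactions (where brute-force enumeration of LP vertices is exact
and fast), calibrates the permutation null with 200 modules × 1,000 draws
(reduced from the 10,000-draw analysis default, which only tightens the
p-value granularity), checks Benjamini–Hochberg exactness on 1,000 random
p-vectors, and exercises the full pipeline on the strong-signal scenario
including a 20-seed shuffled-gene control. All generators and permutation
machinery take explicit seeds, restore the caller's RNG state, and two
pipeline runs with the same config and seed produce byte-identical
artifacts — the run report echoes the config so a run can be reproduced
from its output directory alone.

## Known limitations

* Only production scores are implemented; consumption scoring (the
  symmetric question for uptake) is a listed extension.
* The weight transformation and score normalization are documented package
  defaults; other TIMBR-family variants can be slotted in behind
  `condition_weights()` without touching the LP layer.
* The simplex is dense; genome-scale reconstructions (tens of thousands of
  reactions) would need a sparse solver behind `solve_lp()`'s interface.
* Multi-tissue models are representable through compartment labels, but no
  compartment-topology checking beyond id resolution is performed.
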