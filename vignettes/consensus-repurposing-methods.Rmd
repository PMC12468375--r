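---
title: "Methods: consensus drug repurposing, structural screening and synergy scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus drug repurposing, structural screening and synergy scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
options(consensusDR.quiet = TRUE)
library(consensusDR)
```

`consensusDR` turns stage-labelled transcriptomic case/control cohorts
and the ranked drug lists of signature-reversal repurposing tools into
per-stage drug shortlists, and characterises those shortlists by pathway
enrichment, chemical-structure clustering and drug-combination synergy.
This vignette is the package's account of each method, its assumptions,
the tunable parameters, and the design choices made where the underlying
procedure left room.

## Differential expression and signatures

Expression matrices are assumed to be on a log2 scale. A matrix whose
maximum exceeds 50 is treated as raw intensities and transformed with
`log2(x + 1)`; either decision is logged (`log2_if_needed()`). All
columns are then quantile-normalised onto the mean-of-order-statistics
reference, so every sample shares one value distribution. Tied values
receive the interpolated reference value at their average rank — with
ties the per-column multisets can differ microscopically, which we accept
in exchange for order-invariance.

Per-gene differential expression uses a moderated t-statistic: the pooled
two-group variance of each gene is shrunk toward a prior variance
estimated by fitting a scaled inverse-chi-square distribution across all
genes, using method-of-moments on the log residual variances (the prior
degrees of freedom come from inverting the trigamma function on the
excess spread of `log s²`; the implementation is `moderated_t()` and the
estimator matches the classic empirical-Bayes limma-style scheme to
within sampling error, which the test suite verifies by direct
comparison). The moderated t is referred to a t-distribution with
residual-plus-prior degrees of freedom, and p-values are
Benjamini–Hochberg adjusted. Setting `prior_df = 0` recovers the
ordinary pooled t-test exactly, which pins the limiting behaviour.

When probes rather than genes index the matrix, `collapse_probes()`
keeps, per gene symbol, the probe with the largest `|log2FC|`. Ties
break by smaller adjusted p, then lexicographic probe ID — the rule is
arbitrary but deterministic, which matters more here than the choice
itself.

Signatures are symmetric top lists: among genes with adjusted p strictly
below 0.05, the 150 most over-expressed and 150 most under-expressed by
log2FC (`extract_signature()`, `n_each = 150`, the input ceiling of
common reversal tools). We filter for significance first and rank
second; the alternative order (rank first, then filter) is exposed as
`rank_first = TRUE` because the two readings differ when large-effect
genes are non-significant. Strictness at 0.05 is deliberate: a gene at
exactly 0.05 is excluded. A side with fewer than 150 qualifying genes
returns all of them with a log message rather than an error.

## The consensus score

The package's core is one formula applied at two levels. For item $i$
(drug or pathway) reported by a source at rank $r$ of a $K$-item list,
the normalised rank value is $(K - r + 1)/K$; then

$$\mathrm{Score}_i = w_1 R_i + w_2 A_i, \qquad w_1 = 0.7,\; w_2 = 0.3,$$

with $R_i$ the mean normalised rank value over the sources that contain
the item and $A_i$ the fraction of sources containing it. Level one
aggregates the (truncated, top-50) lists of the repurposing tools within
one dataset; level two aggregates the resulting per-dataset consensus
lists within one stage, ranking each dataset list by its own scores with
average (fractional) ranks for ties. Drugs with a cross-dataset score of
**0.75 or higher** (inclusive) form the stage shortlist.

Two choices deserve emphasis because the formula alone does not fix
them:

* **Rank normalisation.** $(K - r + 1)/K$ maps rank 1 to 1 and rank $K$
  to $1/K$. It is the unique affine choice under which a better rank
  always yields a higher score, the score stays in $[0, 1]$, and a
  universally top-ranked item reaches exactly 1 — which is what makes an
  absolute retention cut at 0.75 meaningful.
* **Absent sources.** $R_i$ averages only over sources reporting the
  item; missing sources are penalised solely through $A_i$. The
  alternative — treating absence as rank $K + 1$, i.e. value 0 inside
  $R_i$ — double-penalises absence and is available as
  `absent_policy = "penalize"` for sensitivity analysis.

Final-score ties break lexicographically by item ID, so output order is
reproducible. Drug identifiers are matched across sources after
case-folding and whitespace collapsing (`harmonize_drug_ids()`), with an
optional user synonym map; no chemical-identity resolution is attempted.
Pathway aggregation reuses the identical machinery with within-dataset
ranks taken from ascending adjusted p-values.

The implementation is verified against a naive loop-based oracle over
every configuration of up to 6 items × 3 tools × 3 datasets, to 1e-12.

## Over-representation analysis

`hypergeom_ora()` computes the upper-tail hypergeometric probability of
the observed query/term overlap. The background universe defaults to the
genes measured on the platform rather than the whole genome — the
conservative standard, and overridable by constructing the
`gene_set_collection()` with a different universe. Terms with zero
overlap are excluded before testing; BH adjustment spans all tested
terms; query genes outside the universe are dropped and counted. The
test suite pins the tail probability to the one-sided Fisher exact test
at machine precision. Drug-target queries are plain unions of per-drug
target genes from a flat drug→target table (Drug Repurposing Hub
schema); the package performs no live database lookups.

## Structural similarity

Two conventions coexist in the similarity layer, both explicit in the
API. Similarity values are bit-set Tanimoto, $|a \wedge b| / |a \vee
b|$, and the clustering distance is the binary Soergel distance
$d = 1 - T$, a metric. Threshold *translation* — turning "Soergel
≤ 0.15" into a similarity percentage — uses the reciprocal convention
$T = 1/(1 + d)$, under which 0.15 corresponds to ≈ 87%. The two
conventions disagree numerically (at $d = 0.15$: 85% vs 87%) and we keep
both on purpose: distances feed the clustering, the reciprocal form is
used only to report threshold equivalents.

Fingerprints from structures are OpenBabel `FP2` hashed topological path
fingerprints, 1024 bits, computed after per-record SMILES validation
(unparsable records are skipped with logged IDs) and salt stripping by
the largest-fragment rule. Any binary fingerprint source works —
heatmap-level similarity values are fingerprint-dependent, so exact
pairwise percentages should not be compared across fingerprint families.

Clustering is agglomerative with **complete linkage**, cut at Soergel
0.15: complete linkage makes the cut a guarantee (every within-cluster
pairwise distance ≤ 0.15, i.e. pairwise Tanimoto ≥ 0.85), which is the
property the planted-cluster recovery tests rely on. Singletons are the
expected regime for structurally diverse shortlists. Cluster labels are
renumbered in order of first appearance, and the tests check that the
induced partition is invariant to input order.

## Synergy models

Dose–response surfaces are percent inhibition on a $[0, 100]$ scale
(viability data should be converted as $100 - v$ first), on dose grids
that include 0; the $(0,0)$ cell is the untreated control. All four
scores are the unweighted mean of observed-minus-expected over the
positive-dose cells — no dose weighting, so adding a constant to every
combination cell shifts every score by exactly that constant (an
invariant the tests enforce).

* **Bliss**: expected $= y_a + y_b - y_a y_b / 100$ with monotherapy
  values from the measured margins.
* **HSA**: expected $= \max(y_a, y_b)$.
* **Loewe**: Hill curves ($y = y_{\min} + (y_{\max} -
  y_{\min})/(1 + (\mathrm{EC}_{50}/x)^h)$) are fitted to both margins by
  Levenberg–Marquardt with slope multi-starts $\{0.5, 1, 2, 4\}$; the
  expected effect of cell $(x_a, x_b)$ solves the isobole equation
  $x_a/D_a(y) + x_b/D_b(y) = 1$ by bisection to an effect tolerance of
  1e-9, where $D(\cdot)$ inverts the fitted curve. Cells whose doses
  saturate both curves are scored against the asymptotic (lower of the
  two maxima) expectation and counted; sham combinations (a drug split
  against itself) score 0 by construction, which the tests verify.
* **ZIP**: Hill curves are fitted to each row and column of the
  combination matrix (free four-parameter fits); the smoothed response
  at a cell is the average of its row-fit and column-fit predictions,
  and the zero-interaction expectation is the Bliss formula evaluated on
  the *fitted* monotherapy margins. Rows/columns with fewer than four
  points or failed fits fall back to raw observations and flag the score
  as degraded.

Classification is strict: a score must exceed +5 for moderate and +10
for strong synergy — +5 and +10 themselves do not qualify.
`classify_and_rank()` builds per-model synergistic lists (score > 5),
top-20 views, the intersection of pairs synergistic under all four
models, and the union annotated with which models fired. Model
divergence is informative rather than a defect: for steep full-efficacy
curves of unequal potency, Loewe's dose-equivalence expectation is the
most demanding and its scores the most conservative; for submaximal
curves ($y_{\max}$ well below 100) the ordering can invert because the
independence null keeps growing where the isobole solution saturates.
The test suite exercises both regimes.

## Synthetic data: what it emulates and what it does not

Every input type has a seeded generator that emits machine-readable
planted truth (`.truth.json` sidecars), and all generators are pure
functions of (parameters, seed) with fixed sub-stream offsets so
components stay independently reproducible.

* `gen_expression()`: i.i.d. Gaussian genes at baseline 8.0 (a typical
  log2 microarray intensity) with planted ±effect shifts in cases.
  Default study conditions: 1000 genes, 100 up + 100 down planted at
  effect 2.0, noise SD 0.5, 20 cases / 20 controls — conditions under
  which signature recovery exceeds 95%, verified by simulation. The
  generator does **not** emulate probe-level artifacts, batch effects,
  gene–gene correlation or platform differences, so passing recovery
  tests demonstrate the pipeline's correctness, not its robustness to
  real microarray pathology.
* `gen_tool_outputs()`: latent-strength model in which planted reversers
  beat decoys in pairwise contests with probability `rank_advantage`
  (Gaussian shift $\mu = \sqrt{2}\,\Phi^{-1}(p)$); scores are synthetic
  inhibition values on $[-100, 0)$, strictly ordered, because only rank
  order carries information downstream. Defaults mirror the study
  conditions: 3 tools, 4 datasets, top-50 lists, advantage 0.9, 25
  planted reversers in a 300-drug universe.
* `gen_fingerprints()`: cluster centres with half the bits set (so
  unrelated fingerprints sit near Tanimoto 1/3) and members derived by
  swapping a fixed number of set bits, chosen so the *worst-case*
  within-cluster pairwise Tanimoto meets the target; infeasible targets
  raise an error rather than being silently clipped.
* `gen_dose_response()`: exact Hill monotherapy margins plus the chosen
  model's null expectation in combination cells, plus a planted constant
  delta and optional Gaussian noise. Under each model's own null with
  zero noise the matching score is 0 (to 1e-9 for the closed-form
  models, 1e-3 through the fitting pipeline).

## Numerical choices and degenerate inputs

* BH adjustment has a single implementation (`bh_adjust()`, wrapping
  `stats::p.adjust`) shared by DE and ORA, checked against a brute-force
  definition.
* Zero residual variance for every gene aborts DE; all-flat
  dose-response data return a flat non-converged Hill fit; an empty
  significant-gene set returns an empty signature with a warning; an
  empty shortlist warns rather than errors, so pipelines report rather
  than crash.
* Responses outside $[-10, 110]$ are clipped into $[0, 100]$ with a
  warning at surface construction; generator output bypasses clipping.
* Hill fits whose best solution is decreasing ($y_{\min} > y_{\max}$)
  are treated as non-converged and handled by monotone interpolation.

## Problem sizes in the test suite

The suite regenerates everything at run time: oracle comparisons use up
to 6 items × 3 tools × 3 datasets; calibration and recovery checks use
100 seeds at 200 genes × 20 samples (type-I error), 100 seeds of the
3 × 4 × 300-drug ranking conditions, and 8 × 8 dose grids for synergy.
These sizes give Monte-Carlo standard errors comfortably inside the
asserted bands while keeping a full run around twenty seconds.

## Known limitations

* Consensus aggregation treats source lists as exchangeable; there is no
  per-tool reliability weighting.
* The moderated t assumes independent genes when estimating the variance
  prior; correlated expression inflates the effective spread.
* ORA ignores gene-set overlap structure (no DAG, no ancestor
  propagation, no term-similarity clustering) — results are flat ranked
  tables.
* Loewe/ZIP scores inherit Hill-fit uncertainty; surfaces with fewer
  than four doses per arm degrade to raw-margin approximations.
* Structure handling is 2D-topological only; stereochemistry and 3D
  conformers are out of scope.
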