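---
title: "Differential hub-gene network analysis: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential hub-gene network analysis: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubnetdiff)
```

## The problem

Paired tumor/normal expression profiles ask two different questions at
once: *which genes change level* between the two tissue states, and
*how the dependence structure among genes rewires*. `hubnetdiff`
answers both with a single pipeline: a paired rank test selects
differentially expressed genes (DEGs); a sparse Gaussian graphical
model is then estimated independently for each tissue state by
per-gene LASSO regressions; highly connected genes ("hubs") are
extracted by weighted degree centrality; and the two networks are
compared through their common hubs, shared edges, cross-projections,
and the intersection of hubs with the DEG set.

## Differential expression

Each gene is tested with the two-sided Wilcoxon signed-rank test on
tumor-minus-normal differences within patients (`wilcoxon_test()`).
The paired variant is the default because the design is paired: each
patient contributes one sample per state, and a shared patient effect
cancels exactly in the within-patient differences.  An unpaired
rank-sum variant is available by configuration.

Numerical conventions, chosen once:

* **Exact null.** For at most 25 pairs the exact two-sided p-value is
  computed by dynamic programming over all $2^m$ sign assignments of
  the nonzero differences; ranks may be tied (half-integer), which the
  enumeration handles by doubling.  Beyond 25 pairs a normal
  approximation with continuity correction is used, with the exact
  null moments $E[W^+]=S/2$ and $\mathrm{Var}[W^+]=\sum_i r_i^2/4$
  (valid under ties and zeros because $W^+$ is a sum of independent
  Bernoulli(1/2)-weighted ranks).
* **Zero differences** follow the Pratt convention by default:
  absolute differences are ranked with zeros included and the zero
  ranks are then dropped.  The drop-first (classic) convention is
  available via `zero_method = "wilcoxon"`.
* **Transform invariance.** The rank-sum test is invariant to any
  strictly increasing transform of the expression scale.  The paired
  signed-rank test is *not* (it ranks difference magnitudes), which is
  why the pipeline runs it on the expression values as provided and
  never re-scales beforehand.

Selection combines two criteria (`bh_select()`): the
Benjamini–Hochberg step-up rule at FDR level $q$ (default
$q = 0.001$), using critical values $(i/m)\,q$ for the gene of rank
$i$ among $m$, **and** a raw p-value ceiling (default $0.001$).  Ties
in p-values share one selection outcome; ties are ordered
lexicographically by gene id for ranking.  Direction (`up`/`down` in
tumor) is assigned by comparing per-group medians of
$\log_2(x+1)$; the log transform is applied only here, where levels
are reported, because the rank tests do not need it.

An alternative *middle-rank* filter (`middle_rank_threshold()`) is
implemented for completeness: it thresholds at the BH critical level
of the gene at rank $\lceil m/2 \rceil$ (capped by $q$) and retains
genes with level strictly below.  The two descriptions of the
selection step are not equivalent — the middle-rank rule is purely
rank-based and can retain at most half the genes — and the step-up
rule is the default because every downstream accounting in the
pipeline uses the combined "$p \le 0.001$ and $p \le p_{adj}$"
criterion.  The discrepancy is documented rather than resolved.

## Network estimation

For each tissue state separately, the conditional-dependence graph is
estimated by neighborhood selection: gene $j$ is regressed on all
remaining genes with an $\ell_1$ penalty,

$$\hat\beta^{(j)} = \arg\min_\beta \tfrac{1}{2n}\lVert x_j - X_{-j}\beta
\rVert_2^2 + \lambda \lVert \beta \rVert_1,$$

and the genes with nonzero coefficients form $j$'s neighborhood.  The
solver is cyclic coordinate descent in covariance form with active-set
passes (`fit_lasso()`, `estimate_neighborhoods()`); the gene–gene Gram
matrix is computed once and shared by all $p$ regressions.
Convergence is declared when no coefficient moves by more than
$10^{-7}$ in a full sweep; fits are deterministic and independent of
gene input order (genes are processed lexicographically).

**The penalty is analytic, not cross-validated** (`mb_lambda()`):

$$\lambda(\alpha) = \frac{\Phi^{-1}\!\bigl(1 - \alpha/(2p^2)\bigr)}{\sqrt{n}},$$

the classical neighborhood-selection calibration that bounds the
probability of falsely joining two disconnected components by
$\alpha$ (default $\alpha = 0.1$, exposed in the configuration).  The
quantile is evaluated through the upper tail directly
(`qnorm(..., lower.tail = FALSE)`); computing $1 - \alpha/(2p^2)$
first would lose about seven significant digits to cancellation at
genome-scale $p$.  Two sizing conventions matter and are both
recorded in every report:

* $p$ in the formula is the number of genes the error control is
  calibrated over — the full post-zero-filter gene count — while the
  regressions themselves run over the DEG-selected subset (the genes
  carried into network analysis).  At $n = 50$ and $p = 17{,}649$ the
  formula gives $\lambda = 0.889294$.
* $n$ is the per-group sample count (the networks are estimated per
  group).

`connectivity_curve()` recomputes the edge count over a penalty grid,
the standard diagnostic for judging the analytic choice; counts are
nonincreasing in $\lambda$ up to solver tolerance.

### Input scale for estimation

Co-expression is modelled on the $\log_2(x+1)$ scale, and each
sample's mean log-expression (over all genes) is removed before
per-gene standardization (`standardize_group()`).  Both steps default
on and are separately switchable.  The reasons:

* Normalized expression is approximately lognormal; correlations
  estimated on the raw scale are attenuated by the convexity of the
  exponential, which costs real edges at a fixed penalty.
* Sample-level offsets — residual sequencing depth, patient-specific
  shifts — act as a common factor that induces weak positive
  correlation between *every* gene pair.  At genome scale this is the
  classic motivation for size-factor normalization; removing the
  per-sample mean on the log scale is its direct analogue here, and
  without it neighborhood selection reports a large number of
  factor-driven edges that reflect no gene-pair-specific dependence.

Per-gene standardization then uses mean 0 and sample standard
deviation 1 ($n-1$ denominator) within each group; zero-variance
genes are dropped with a warning.

### Symmetrization and weights

Directed neighborhoods are merged by the **OR rule** by default: an
undirected edge joins $i$ and $j$ when either regression selected the
other gene; the AND rule (both directions required) is available.  OR
is the default because hub accounting downstream is defined on the
union-style neighbor sets, and because at a conservative analytic
penalty the OR rule loses fewer true edges.  The edge weight is the
mean of the available absolute coefficients (one or two values per
edge) — a proxy, on standardized data, for the strength of the
conditional association; it is not claimed to equal the partial
correlation.

## Hubs and hub-of-hubs

Candidate hubs are all nodes with degree $\ge 1$
(`node_candidates()`).  A hub (`select_hubs()`) is a candidate whose
edge-weight sum *and* degree both reach their cutoffs; the default
cutoff for each statistic is its mean over candidates, compared
**inclusively** ($\ge$).  Inclusive comparison is the default because
the hub accounting treats values exactly at the mean as qualifying; a
strict mode exists.  Explicit cutoff pairs can override the means, so
a published cutoff pair can be applied verbatim.  The weight cutoff
applies to the per-node weight *sum*, matching the definition of the
node statistic.

Hub-of-hubs (`hub_of_hub()`) induce the subnetwork on hub genes only,
recompute degree and weight sum inside it, and keep members with
induced degree $\ge 2$ — a gene connected to a single other hub is
not a hub among hubs.  The same mean-based cutoff logic then flags a
`selected` top tier within the induced graph.

`scale_free_fit()` regresses $\log_{10}$ node frequency on
$\log_{10}$ degree over the raw (unbinned) degree histogram, degrees
$\ge 1$ only; at least three distinct degrees are required, and a
constant response is reported as slope 0 with $R^2 = 0$ by contract.
No logarithmic binning is applied.

## Cross-group comparison

All comparisons are set arithmetic over gene identifiers, treated as
opaque strings throughout:

* `common_hubs()` — intersection and differences of the two hub sets,
  with the share of each side that is common.
* `shared_edges()` — per common hub, the neighbors adjacent in both
  networks (symmetric in the two networks).
* `project_hubs()` — one group's hubs evaluated in the other group's
  full network: a hub is "identified" there when it retains degree
  $\ge 1$; summaries cover identified counts, degree ranges, and
  overlap with the home edge sets.
* `intersect_deg_hubs()` — the three-way Venn decomposition of DEG
  set and both hub sets, each hub category split by direction, and
  the headline list: common hubs inside the DEG set.
* `retest_hub_significance()` — the DEG criterion reapplied with the
  multiple-testing burden $m$ restricted to the union of hub genes.
  This is an interpretation of a second significance pass over hub
  genes; the smaller universe loosens the BH critical values, so hub
  genes can reach significance here that missed the genome-wide cut.

All reported percentages are recomputed from their integer
numerator/denominator pairs and rounded half-up to one decimal
(`pct()`), so printed percentages and printed counts can never
disagree by more than 0.05.

## The synthetic generator

Real tumor-cohort data cannot ship with the package, so every claim
the test suite makes is scored against planted ground truth from
`make_precision()` / `generate_paired_study()` / `simulate_study()`:

* **Planted graphs.** Chain, hub-star, preferential-attachment and
  Erdős–Rényi topologies; edges get precision entries $\pm$`magnitude`
  with random signs; the diagonal starts at 1 and is boosted uniformly
  by exactly the amount that brings the smallest eigenvalue to 0.1.
  The uniform boost inflates the diagonal as little as positive
  definiteness allows, keeping the implied partial correlations as
  strong as possible; configurations whose boost would push them
  below 0.05 are refused as infeasible.
* **Paired samples.** Per patient, a shared scalar effect (log2 scale,
  sd 0.5 by default) is added to both samples, making the paired test
  meaningfully more powerful than the rank-sum test on the same data
  — the generator-level justification for the paired default.
* **Expression scale.** Latent Gaussian log2 values on per-gene
  baselines (uniform 4–12 by default) are mapped through
  $\max(2^x - 1, 0)$, so files look like nonnegative normalized
  counts.  An optional fraction of genes is planted at a low baseline
  to exercise the zero filter.
* **Differential expression** is planted as per-gene log2 shifts on
  the tumor side, with known direction.

Presets fix the study conditions used by the tests: `null`
(exchangeable groups, shared Erdős–Rényi truth of mean degree 2,
magnitude 0.3), `de_only` (10% of genes shifted by $\pm 1.5$),
`rewire` (two hub-star truths, 10% of genes as centers, magnitude
0.35, 30% of centers shared), and `paperlike` (independent
preferential-attachment truths, 15% DE genes with shifts of 1–2, 5%
low-expression genes).

What the generator deliberately does **not** emulate: count-level
noise (no library-size variation, negative-binomial dispersion or
zero inflation), annotation structure, or batch effects beyond the
scalar patient offset.  Passing tests therefore demonstrate that the
pipeline's statistics and accounting are correct and that estimation
recovers planted structure under Gaussian-copula data of realistic
size — not that any particular biological cohort would yield the same
gene lists.

## Test and calibration scales

The suite keeps every experiment at sizes a single CPU handles in
seconds to minutes: exact-test oracles enumerate up to $2^8$ sign
assignments; BH selection is compared against brute-force threshold
search for $m \le 12$ over a thousand random instances; the null
calibration runs 500 replicates at $p = 20$ genes and 10 pairs; the
recovery experiment uses the `rewire` preset at $p = 60$ genes and
200 pairs over 10 seeds, where the pipeline's planted-edge F1 and
planted-hub recovery are held above 0.6 and 50% as regression guards;
and the family-wise null-error experiment for the DEG stage uses
2,000 replicates at 5 genes and 8 pairs.  All replicate experiments
fix explicit seeds, and Monte-Carlo assertions allow three binomial
standard errors.

## Known limitations

* The analytic penalty is conservative by construction; at small $n$
  it can leave a network empty.  The pipeline then reports empty hub
  sets with a warning rather than failing, and
  `connectivity_curve()` is the recommended diagnostic.
* Edge weights are absolute LASSO coefficients (averaged across the
  two directed fits), not partial correlations; they order edges
  sensibly on standardized data but have no exact population
  interpretation.
* The hub-universe re-test implements one reading of a second
  significance pass over hub genes; the choice of universe is
  documented, not canonical.
* Networks are estimated per group independently; no joint estimation
  (graphical lasso with shared structure, stability selection, or
  cross-validated penalties) is attempted — the pipeline fixes one
  analytic penalty by design.
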