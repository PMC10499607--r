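---
title: "Regulome inference from paired single-cell expression and accessibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regulome inference from paired single-cell expression and accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulokit)
```

# The model and its assumptions

regulokit infers a gene regulatory network (GRN) from observations that
carry both a transcriptome and a chromatin-accessibility profile —
typically metacells or pseudocells built from paired scRNA/scATAC data.
For each target gene the model is a linear interaction regression

$$Y_i = \sum_j \beta_j\, e_j\, a_j + \varepsilon,$$

where $Y_i$ is the target's log-normalized expression, $e_j$ the
log-normalized expression of transcription factor $j$, $a_j$ the
accessibility probability of the region carrying $j$'s predicted binding
site, and $\varepsilon$ Gaussian noise. The product term encodes the
biological assumption that a TF acts on a target only where its binding
site is accessible: a closed region silences the term regardless of TF
abundance. The model is fit by ordinary least squares (Gaussian noise,
identity link) with an intercept; each coefficient is tested with the
single-term ANOVA F-test, which for OLS equals the two-sided t-test on
the coefficient.

Assumptions worth keeping in mind: expression and accessibility are
treated as noise-free regressors (errors-in-variables attenuate
$\hat\beta$); effects are additive across TF-region pairs; and the
log-normalized scale is taken as given. Regularized back-ends (ridge,
lasso, elastic net via glmnet) and gradient boosting (xgboost) are
available through `fit_target_model(method = ...)` but return
coefficients or importances without p-values; only the default OLS path
feeds the significance pipeline.

# The pipeline

1. **Candidate regions** (`select_candidate_regions`). ATAC peaks are
   width-filtered (strictly more than 20 bp and less than 10,000 bp),
   clipped to their overlap with conserved elements, stripped of any base
   overlapping an exon, separately clipped to cCRE overlap, and the union
   of the two branches is merged. Clipping (rather than keeping whole
   peaks) makes exon subtraction well defined; the exon filter applies
   only to the conservation branch, since exonic sequence is conserved
   for reasons unrelated to regulation while cCRE evidence is already
   regulatory. Each merged row carries a provenance flag (`conserved`,
   `cCRE`, `both`). The whole operation is equivalent to a per-base
   boolean mask, which the tests use as an oracle, and is idempotent.

2. **Motif scan** (`scan_regions`). PFMs become log-odds matrices against
   a background model (uniform by default — reproducible and free of
   dataset-specific tuning; a custom background is a parameter) with a
   pseudocount of 0.8. Scores are discretized to 0.01-bit bins and the
   score threshold for the per-window p-value (default `5e-5`) is
   computed from the exact score distribution by dynamic programming, so
   the scan is deterministic and matches an exhaustive per-window scorer
   bin-exactly. Both strands are scanned; windows containing non-ACGT
   bases are skipped; overlapping hits are all reported since the GRN
   uses region-level presence only. TFs without a motif can borrow motifs
   from sequence-similar family members
   (`assign_motifs_by_similarity`): global Needleman-Wunsch alignment
   (BLOSUM62, gap opening 10, gap extension 0.5 — the alignment
   parameters are exposed, since different suites default differently),
   members with at least 20% identity qualify, and the motifs of the
   three most similar members are adopted. Direct motif evidence always
   outranks family-inferred assignments during deduplication.

3. **Gene-region assignment** (`assign_regions_to_genes`). A region is
   assigned to every gene whose regulatory window — gene body plus 100 kb
   upstream of the TSS, strand-aware — it overlaps by at least 1 bp. No
   reciprocal-overlap fraction and no down-weighting of multi-gene
   regions: the simplest defensible rule, recorded here because the
   choice is genuinely open.

4. **Model fitting** (`infer_grn`). One column per distinct (TF, region)
   pair; duplicate pairs collapse; self-loops (TF = target) are excluded
   because the response would appear on both sides; TFs detected in fewer
   than 5% of observations are dropped at design time, mirroring the
   branch-pruning detection rule and preventing near-constant columns.
   Rank-deficient designs drop aliased columns in term order,
   deterministically. P-values are pooled across **all** target models
   into a single Benjamini-Hochberg correction — stricter than per-target
   pooling, and the natural reading of a network-wide FDR; edges with
   FDR < 0.05 are retained and per-TF modules are split by coefficient
   sign. When candidate regions are sub-intervals of the peaks that name
   the accessibility rows, `map_regions_to_peaks` routes each candidate
   to its enclosing peak's accessibility profile.

# Coarse-graining

`make_pseudocells` draws 30% of cells as seeds (round-half-up), builds
each seed's territory from its ten nearest neighbours in the top-20-PC
space of z-scaled expression (the 2,000 most variable genes), resolves
multi-territory cells uniformly at random on the seeded RNG stream, and
aggregates expression as means and accessibility as means of binarized
counts. The seed belongs to its own territory — the natural reading where
the source procedure is silent. `lsi` is tf-idf (term frequency scaled by
`log(1 + N/df)`) followed by truncated SVD with component 1 retained;
dropping a depth-correlated first component is common elsewhere but is
left to the caller. `cluster_high_resolution` runs Louvain on an
unweighted symmetric kNN graph (k = 20, Euclidean) at resolution 100 by
default; k is exposed since the source procedure does not state it.

# Branch-specific pruning

For each region, accessibility probabilities across high-resolution
clusters get a trimmed z-transformation: the per-cluster mean ATAC depth
is regressed out first, then the mean and s.d. are computed only over
clusters whose residual lies within the 5th-95th percentile band (the
trimming is applied to residuals because the covariate is removed before
the transformation). Close outliers are clusters with BH-adjusted
$\Phi(z) < 0.01$, open outliers the upper-tail analogue. A step-wise rule
then defines where a region is accessible: except close outliers if any
exist; only open outliers otherwise; everywhere when there are no
outliers. Metacells inherit their cluster's accessibility, and a
two-sided chi-squared test (no continuity correction; Haldane-Anscombe
0.5 for odds ratios with empty cells) flags regions whose accessible
metacells are depleted in a branch (FDR < 0.01 **and** OR < 0.5).
Pruning drops edges through branch-inaccessible regions, then all edges
of TFs detected (expression strictly greater than 0) in under 5% of the
branch's observations.

An operating-regime caveat the tests make explicit: the percentile
trimming can only expose outlier clusters that are *rare* (below roughly
the 5% trim tail). A region closed in a full third of clusters leaves
the band containing both modes, the trimmed s.d. large, and
$z \approx -1.4$ — no outlier call. The outlier machinery is therefore
validated on rare-outlier constructions, and the pruning chain is
validated from depletion testing onward, where closure of any size is
detectable.

# Module activity

`gene_module_score` bins pool genes into 24 average-expression bins and
samples 100 control genes per module gene from the non-module genes of
its bin (nearest non-empty bin as fallback); the score is the module mean
minus the control mean per observation. Excluding module genes from their
own control draws departs from the common convention on purpose: a
shifted module otherwise monopolizes its bin, becomes its own control,
and an additive shift of +1 scores far below 1. With exclusion, a null
module scores ~0 and a +1-shifted module ~+1.
`regulatory_module_deviation` is a background-matched z-score (50 random
region sets drawn from accessibility-matched decile bins) — a simplified
analogue of permutation-based deviation scores, not a bit-for-bit
reproduction. `variance_explained` reports the R² of activity ~ branch,
~ pseudotime, and ~ both; `differential_module_activity` compares
branches by two-sided Wilcoxon on the top 30% of pseudotime and ranks
FDR < 0.05 up-modules by mean difference. `branch_activation_score`
averages per-gene correlations (Pearson default, Spearman available —
different figures in this analysis family use either) between module-gene
expression and branch probabilities, then z-scores the module means with
the sample (n−1) standard deviation, so two modules with means {1, −1}
score ±1/√2.

# Screen statistics

`assign_guides` fits a two-component, free-variance Gaussian mixture to
natural-log nonzero UMI counts and assigns entries with posterior ≥ 0.5
for the higher-mean component; zero counts are never assigned; fewer than
ten usable values falls back to a fixed ln-count threshold with a
warning. `perturbation_probability` fits one multi-response elastic-net
model (alpha = 0.5, shared cross-validated lambda) of the 500
most-variable features on covariates plus guide indicators, then converts
the squared-error difference between the full fit and the fit with a
guide zeroed into $p = \mathrm{logistic}\big((\mathrm{SSE}_0 -
\mathrm{SSE}) / (2\sigma^2)\big)$, with $\sigma^2$ defined here as the
mean squared residual of the full fit over all cells and selected
features (the source leaves $\sigma^2$ unstated). The SSE difference is
summed over all selected features, not only those with non-zero
coefficients. Guide-free cells get $p = 0$; guides with fewer than five
carriers are reported missing; target-level probabilities take the
maximum over the target's guides.

`composition_enrichment` tests each guide-branch pair with the
organoid-stratified CMH statistic (classical 1-df form, no continuity
correction, implemented from the closed form and cross-checked in the
tests against an independent implementation) plus per-organoid Fisher
tests. Filter 1 requires per-organoid significance (Fisher FDR < 0.05) in
more than one organoid with a consistent direction; filter 2 requires the
same branch-direction effect at CMH FDR < 0.01 from at least one other
guide of the same target; which test carries which threshold follows the
order in which the two requirements are stated. Survivors pool per target
into the log odds ratio (natural log; 0.5 added to all four counts when
any is zero), and the per-target maximum LOR across branches is the
composition-change measure.

# Differential tests and binding scores

`de_linear` is the vectorized per-gene OLS with an F-test on the
condition coefficient (equal to the classical equal-variance t-test when
no covariates are given); `de_wilcoxon` the exact-when-small rank-sum
test with a log-fold-change effect; `da_binomial_lrt` the binomial
logit GLM against the fragment-count-only null with a 1-df LRT. Perfect
separation is handled by refitting both models with four half-weight
pseudo-observations that balance condition against outcome — a weakly
informative fallback, flagged per row, chosen over penalized-likelihood
fits to stay within base R. `stage_specific_peaks` needs per-stage
observation counts to aggregate the "all other observations" denominator;
percentages alone cannot provide it, so the operation takes stage sizes
(equal by default). `gene_binding_score` sums intensity-times-bases over
the gene body plus a 2-kb strand-aware upstream promoter extension;
`both_sides = TRUE` extends downstream too, since "gene body + 2 kb" can
be read either way.

# Fate-graph branch assignment

`transition_scores` rank-normalizes absorption probabilities per terminal
state (average ranks, divided by the observation count), making the
scores invariant to monotone transforms. `build_fate_graph` connects
nodes to their k = 30 nearest neighbours in transition-score space, keeps
edges with connectivity above 0.2, and orients them strictly forward in
pseudotime (ties are dropped — the source addresses only the strict
case). `assign_branches` runs 10,000 backward random walks of 200 steps
from each tip (auto-selected as the node maximizing the product of
transition-score and pseudotime ranks, unless given); a node takes a
single tip's identity when its visitation frequency exceeds 100 times the
next tip's, otherwise the combined identity of all tips within that
ratio. The hard-coded merged labels of the original analysis
("telencephalon", "early") generalize to a caller-supplied merge map.
Walks hitting a node with no backward edge stop early and count what they
visited; unreached nodes inherit the label of their highest-connectivity
neighbour, and isolated unreached nodes are `"unassigned"`.

# The synthetic generator: what it does and does not emulate

`simulate_regulome` is first-class, tested code, not a fixture. TF
expression follows smooth Gaussian-bump trajectories over pseudotime with
branch-specific modulation after a branch point at 0.3; accessibilities
are smooth logistic curves in [0.3, 0.9] with a fraction (default 10%)
of wired regions set to exactly zero in one random branch; target
expression is computed literally from the model above and floored at 0
(log-normalized expression is nonnegative); every wired (TF, region) pair
gets the TF's motif consensus written into the genome at a recorded
offset — the argmax-per-column consensus guarantees scan hits without
threshold tuning — and one decoy region with an unwired TF's motif sits
in each target's window so that downstream FDR tests have true null
terms. Observation counts, noise level (`noise_sd = 0.1`) and sizes used
by the tests (10 TFs, 200 targets, 500 observations for recovery; 100
targets and 20 seeds for null calibration; 2,000 cells and 30% escapers
for the screen) are the generator's study conditions.
`simulate_screen` adds bimodal guide UMI counts (log-normal mixture),
organoid-wobbled branch log-odds with target-specific shifts, and an
escaper fraction of carrier cells that stay phenotypically wild type —
the very situation the perturbation-probability model exists to handle.

What the generator does **not** emulate: count-level overdispersion and
dropout, doublets, batch effects, genuinely correlated TF programs,
chromatin velocity, or realistic organoid biology. Passing tests
demonstrate that the algorithms recover what they are defined to recover
under their stated model; they do not certify performance on real
single-cell noise.

# Numerical choices and degenerate inputs

- Score discretization for motif p-values: 0.01-bit bins; the scanner
  and the DP threshold use the same binned matrix, so oracle agreement
  is exact rather than approximate.
- Trimmed z: a trimmed s.d. below 1e-10 (or residuals all numerically
  zero, e.g. a covariate proportional to accessibility) marks the region
  degenerate with z = 0 rather than amplifying float noise.
- UMAP embedding of the TF score matrix deduplicates identical rows and
  assigns shared coordinates, because stochastic layout optimization
  would scatter exact duplicates; the embedding is single-threaded and
  seed-deterministic.
- BH corrections: pooled globally for GRN edges; per region across
  clusters for outlier calls; across regions within branch for depletion;
  across all tests of a kind in the screen.
- Aliased columns, empty clusters, all-zero matrices, zero-margin
  contingency tables and unreachable graph nodes all have defined,
  tested behaviour (drop-and-report, errors, p = 1, or documented
  fallbacks) rather than NA propagation.
- Problem sizes in the test-suite simulations (hundreds of observations,
  tens of TFs, 1,000-feature null panels, 20-seed calibration loops) were
  chosen to make the statistical assertions stable at desk scale while
  the full suite stays fast.

# Known limitations

- OLS on floored (nonnegative) responses attenuates coefficients when
  flooring binds; the generator's conditions keep flooring rare but real
  data near zero expression will bias $\hat\beta$ toward 0.
- The trimmed-z outlier analysis cannot flag accessibility modes that
  cover more than the trim tail (see above); branch-level closure
  detection in practice rides on the chi-squared depletion step.
- The perturbation-probability model shares one cross-validated lambda
  across features; per-feature regularization would be slower and is not
  implemented.
- Shortest-path KO direction prediction uses unweighted hop counts;
  whether the original analysis weighted edges is unknown.
- Family-similarity motif assignment depends on alignment parameters that
  the original database construction did not publish; the defaults here
  are reasonable, exposed, and not claimed to match the original.
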