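---
title: "Quantifying reproductive isolation from diallel crosses: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying reproductive isolation from diallel crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossiso)
```

## The problem

Interspecific hybridization in crop wild relatives (the motivating system is
a diallel among wild *Cucumis* species and melon) fails at a sequence of
reproductive stages: pollen tubes may be arrested along the pistil
(post-mating, pre-zygotic), and crosses whose ovules are fertilized may still
fail at fruit set, produce underweight fruits, or set few or inviable seeds
(post-zygotic). `crossiso` turns replicated pollination records into
quantitative statements about where isolation acts, how much each stage
contributes to total isolation, how barrier traits behave genetically in F1
hybrids, and whether barrier strength tracks genetic divergence.

## Crossability index

Each directed cross is summarized on an ordinal 1–8 scale by
`classify_crossability()`. Levels 5–8 are pre-zygotic: they encode the modal
pollen-tube arrest site across replicate pistils scored 24 h after
pollination on the 0–4 progression scale (0 = halted before the stigma half,
4 = fertilizing ovules). Levels 4 down to 1 are post-zygotic: fertilization
or fruit without germinating seed (4), germinating but inviable or fully
sterile hybrids (3), viable hybrids retaining at least one fertile function
(2), and fully fertile self- or intraspecific crosses (1, reserved).

Two points were genuinely open and are fixed here:

* **Levels 2 vs 3.** Level 2 requires viable hybrids with at least one
  fertile function (male-sterile but female-fertile hybrids qualify); level
  3 covers inviable or fully sterile progeny, including germination below
  10% with seedling death. This matches the narrative order in which hybrid
  quality degrades.
* **Replicate aggregation for arrest sites.** The modal score decides levels
  5–8, with ties broken toward the more severe (higher) level — a
  conservative barrier call. The alternative (furthest tube observed) would
  systematically understate barriers with any replicate-to-replicate noise.

When the available fields cannot decide (e.g. germinating seed but unknown
hybrid fate), the classification is an explicit `undetermined`, never a
silent default. `ci_to_pollen_scale()` maps levels back onto the 0–4 scale
(8→0, 7→1, 6→2, 5→3, 1–4→4) for use as a quantitative trait.

## Stage-wise reproductive isolation

For each of four life-history stages — pollen–pistil compatibility (mean 0–4
score), fruit set (fruits per pollination), fruit weight (mean weight per
harvested fruit), and seed production (seeds per mature fruit) — the success
of a directed cross is standardized by the seed parent's self-pollination:

\[ RI = 1 - \frac{\text{interspecific success}}{\text{self success}} , \]

clamped to 0 when the cross outperforms selfing. Clamping is applied per
direction *before* reciprocal averaging, matching the order in which the
source equations are stated. A selfing value of zero or missing makes the
direction unassessable (excluded) rather than dividing by zero. A direction
with zero fruit set has fruit-set RI 1 and is missing for the later
post-zygotic stages — this is why the assessable pair count drops between
the pre- and post-zygotic stages.

Sequential contributions follow the Ramsey decomposition: with stages in
life-history order,

\[ AC_1 = RI_1, \qquad AC_n = RI_n \Big(1 - \sum_{i<n} AC_i\Big), \qquad
   T = \sum_n AC_n, \qquad RC_n = AC_n / T . \]

The recurrence telescopes, \(1 - T = \prod_n (1 - RI_n)\), which the test
suite checks to \(10^{-12}\) (as an absolute difference — the identity
underflows relatively when \(T \to 1\)). The published four-stage table is
internally consistent with applying the recurrence to stage means taken over
each stage's own assessable pair set (the absolute column sums to the
printed total), so that is the default aggregation (`mode = "stage_means"`);
a per-pair-then-average mode is available behind a flag for pair sets that
are complete at every stage.

## Gene action in F1 hybrids

For a trait measured on both parents and the F1, `gene_action()` reports the
dominance deviation \(d = \bar F_1 - (\bar P_1 + \bar P_2)/2\), the additive
value \(|a| = |\bar P_1 - \bar P_2|/2\), and the degree of dominance
\(d/|a|\). Because both \(d\) and \(|a|\) are symmetric in the parents, the
ratio is invariant under relabeling the parents; the *direction* of
dominance is reported separately (`toward`). Significance of the deviation
uses the midparent contrast \(F_1 - \tfrac12 P_1 - \tfrac12 P_2 = 0\) in a
one-way fixed-effects ANOVA: \(SS = d^2 / \sum c_i^2/n_i\) with
\(c = (-\tfrac12, -\tfrac12, 1)\), pooled within-class variance as the
error, \(F\) on \((1, N-3)\) df. Classification bands on \(|d/|a||\) —
below 0.25 additive, 0.25–0.75 partial dominance, 0.75–1.25 dominance,
beyond 1.25 overdominance — are conventional quantitative-genetics cutoffs
(the source uses the words without numbers) and are configurable.

## SNP genotypes, filtering, distance, tree

`read_genotypes()` reads biallelic SNPs from VCF (multiallelic and non-SNP
records skipped with counts). Genotypes of any ploidy are accepted; under
pseudodiploid scoring every heterozygous class collapses to a single AB
call, which is how allotetraploid accessions are handled. Per-genotype depth
comes from `DP` or summed `AD` and is required unless explicitly waived.

`filter_sites()` applies the published cascade in a fixed order: genotypes
below depth 10 become missing; sites with any missing call are dropped; then
monomorphic sites; then sites whose heterozygous fraction exceeds 0.80 (a
mapping-bias guard, interpreted per site); finally greedy left-to-right
thinning per chromosome with a 20 bp minimum spacing. The greedy rule keeps
a site iff it lies ≥ 20 bp beyond the last kept site — it is documented,
deterministic, and idempotent; the upstream read-level filters (read count
and mapping quality) belong to variant calling and are out of scope.

Nei's (1972) standard distance treats each sample as a population with
per-locus allele frequencies in {0, ½, 1}: with per-locus identities
\(j_x = \sum_a x_a^2\), \(j_y\), \(j_{xy}\) averaged arithmetically over
loci, \(I = J_{xy}/\sqrt{J_x J_y}\) and \(D = -\ln I\). Identities slightly
above 1 are clamped; \(I = 0\) yields a documented large sentinel
(\(-\ln \epsilon \approx 36.04\)) instead of infinity. Loci missing in
either member of a pair are excluded pairwise (moot after the no-missing
filter, needed for unfiltered use).

`nj_tree()` is a from-scratch Saitou–Nei agglomeration with two
deterministic choices: ties in the Q criterion (within 1e-12) break toward
the lexicographically smallest sorted label pair, making the result
invariant to input order; negative branch lengths are set to zero with the
difference transferred to the sibling edge (standard practice, flagged).
`bootstrap_tree()` resamples loci with replacement, recomputes distance and
tree, and scores each internal bipartition of the full-data tree as a
percentage of non-degenerate replicates; degenerate (all-zero or non-finite)
replicate matrices are skipped and the denominator adjusted. `ape` provides
the `phylo` container and Newick I/O, and `ape::nj` serves as an independent
oracle in the tests.

## Matrix statistics

`mantel()` correlates the lower triangles of two labeled distance matrices
and permutes one matrix's labels jointly on rows and columns, with
\(p = (\text{hits} + 1)/(n_{\text{perm}} + 1)\). The default is 9,999
permutations, one-sided "greater", because the scientific hypothesis is a
positive isolation–distance association; an exact mode enumerates all
\(n!\) relabelings for small \(n\) (the identity is then included in the
denominator). When matrices have missing entries (pairs unassessable
post-zygotically), taxa with missing values are dropped listwise so the
permuted submatrix is complete. `cluster_heatmap()` reproduces the numeric
contract of a ClustVis-style heatmap: unit-variance column scaling,
1 − Pearson dissimilarities between profiles, and average linkage for both
margins; figure rendering is deliberately out of the tested contract.

## The synthetic world

`synth_config()` states one world and the tests live in it; nothing is tuned
per test. Defaults: 6 taxa (a 6 × 6 diallel), 2,000 biallelic loci, a
balanced unit-branch species tree, substitution rate 0.05 per locus per unit
branch, residual heterozygosity 0.004 (matching the ~0.3–0.4% observed in
inbred-ish wild accessions), negative-binomial depths with mean 30 (size 10)
so the depth filter is exercised, positions with ~40 bp mean spacing so
thinning is exercised, 25 pollinations per directed cross for the fruit/seed
experiment and 5 pistils (10 in the recovery property) for the pollen-tube
experiment — the replication the emulated design states.

Barrier strengths come from a monotone map of pairwise tree distance.
Default is linear in relative distance, \(b_{\text{stage}} =
\min(1, s_{\text{stage}} \, d / d_{\max})\), with slopes 1.25
(pollen–pistil), 1.0 (fruit set), 0.7 (fruit weight), 0.8 (seed viability
and germination): the pre-zygotic barrier saturates first, so the most
diverged pairs are fully pollen-arrested — the pattern the motivating data
show — while post-zygotic barriers remain partial at intermediate
divergence. A constant map provides the null world for calibration. Selfing
baselines vary per taxon (fruit set uniform on 0.5–0.9, etc.) to exercise
standardization.

Stage outcomes are drawn so the expected stage-wise RI equals the stage
barrier: pollen scores are Binomial(4, 1 − b); fruit set is
Bernoulli(s_self (1 − b)); fruit weight gamma with mean scaled by (1 − b);
seeds per fruit Poisson; germination binomial. One stated coupling was
resolved deliberately: gating fruit set on the 24 h pollen score would make
the measured fruit-set RI absorb the pollen barrier
(\(1-(1-b_p)^4(1-b_f)\)), destroying the recovery identity — and the
emulated experiments themselves report crosses with no tubes at the ovules
at 24 h that nevertheless set 40–50% fruit. Fruit set is therefore blocked
only by *complete* pollen arrest (b = 1), and otherwise independent of the
pollen draw. An optional `asymmetry` parameter perturbs barriers per
direction to create unilateral-incompatibility-like patterns.

**What a green test does and does not establish.** The generator has no
linkage, no coalescent variance, no shared polymorphism, no GBS missingness
structure, and symmetric barriers by default; recovering barriers and
topology here validates the estimators' arithmetic and the pipeline's
plumbing, not robustness to real GBS data. The published SNP count,
heterozygosity percentages and observed correlation values depend on the
archived sequencing deposit and are deliberately not reproduction targets;
property-based checks replace them.

## Numerical and testing choices

* Tolerances: exact identities at 1e-12 (absolute where the quantity can
  underflow), least-squares agreement at 1e-8, distance oracles at 1e-10.
* Stochastic acceptance checks run on fixed seed panels scaled to a small
  CPU budget; a stated rate (e.g. "≥ 90% of seeds") is asserted at the
  one-sided binomial bound implied by the panel size (20/25 for a 90% rate,
  false-failure probability 0.033), never loosened beyond that
  finite-sample allowance. Measured behavior of the default world: per-seed
  recovery MAE ≤ 0.1 holds in ≈ 90% of seeds (the fruit-set stage, a ratio
  of binomial proportions at n = 25, is the binding constraint), Mantel
  power against the monotone world is ≈ 100%, and null rejection is ≈ 5%.
* Individual RI entries at 25 Bernoulli replicates have sampling noise
  larger than 0.1; accuracy statements are therefore about mean absolute
  error over pairs, not single entries.
* Determinism: every stochastic routine takes an explicit seed; the
  pipeline refuses stochastic stages without one and reruns are
  byte-identical.

## Known limitations

Backcross/F2 generation-means analysis, partial Mantel tests, imputation,
and maximum-likelihood trees are out of scope. The crossability decision
table cannot distinguish "early/late" arrest sub-types within the stigma or
ovary beyond the four modal scores. Nei's distance on individuals (not
population samples) inherits the pseudodiploid AB scoring's compression of
allele-frequency information for polyploids.
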