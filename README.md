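# crossiso

Quantitative analysis of interspecific reproductive barriers from diallel
crossing experiments, for plant reproductive biologists and breeders working
with crop wild relatives (the motivating system is wild *Cucumis* and melon).

The package covers the full chain from raw pollination records and SNP
genotypes to the statements such studies make:

* **Crossability index (CI).** Each directed cross is classified on an
  ordinal 1–8 scale, from fully fertile selfings (1) through post-zygotic
  failures (fruit/seed/hybrid fertility, 2–4) to pollen-tube arrest at the
  ovary or stigma (5–8), using the modal arrest site across replicate
  pistils.
* **Stage-wise reproductive isolation.** For the sequential stages
  pollen–pistil compatibility, fruit set, fruit weight and seed production,
  `RI = 1 − (interspecific success / self success)`, clamped to [0, 1] per
  direction and averaged over reciprocals. Sequential contributions follow
  the Ramsey decomposition `AC_n = RI_n (1 − Σ_{i<n} AC_i)`, `T = Σ AC_n`,
  `RC_n = AC_n / T`, so `1 − T = Π (1 − RI_n)`.
* **Gene action.** Degree of dominance `d/|a|` with
  `d = F̄₁ − (P̄₁ + P̄₂)/2`, `|a| = |P̄₁ − P̄₂|/2`, and the midparent
  contrast F test on (1, N − 3) df.
* **Genetic distance and tree.** VCF → biallelic SNP matrix (pseudodiploid
  scoring for polyploids) → the published filter cascade (genotype depth
  ≥ 10, no missing data, site heterozygosity ≤ 0.80, 20 bp thinning) →
  Nei (1972) distance `D = −ln I` → neighbor-joining tree with bootstrap
  supports.
* **Isolation–distance association.** Pearson correlation on pair values
  and a Mantel permutation test, plus the clustered-heatmap computation
  (unit-variance column scaling, correlation distance, average linkage).
* **Synthetic data.** A ground-truthed generator (`synth_config()`,
  `simulate_genotypes()`, `simulate_diallel()`) emulating near-homozygous
  taxa diverging along a known tree with barrier strength increasing with
  divergence, so every stage of the pipeline is testable offline.

## Worked example

```r
library(crossiso)

cfg <- synth_config(seed = 7)              # 6-taxon diallel, 2000 SNPs
sim <- simulate_genotypes(cfg)
rec <- simulate_diallel(cfg, sim$truth)

summ <- aggregate_crosses(rec, fertility = synth_fertility(sim$truth))
ci_matrix(summ)$levels
#>       male
#> female sp01 sp02 sp03 sp04 sp05 sp06
#>   sp01    1    2    2    8    8    8
#>   sp02    2    1    2    8    8    8
#>   sp03    2    2    1    8    8    2
#>   ...
```

Close relatives hybridize (CI 2); the most diverged pairs are fully
pollen-arrested at the stigma (CI 8); selfings are fully fertile (CI 1).

```r
ct <- contribution_table(ri_matrices(summ))
ct
#>                         stage  n   mean_RI         AC         RC
#> pollen_pistil   pollen_pistil 15 0.7966667 0.79666667 0.81386502
#> fruit_set           fruit_set 15 0.7519358 0.15289362 0.15619427
#> fruit_weight     fruit_weight  7 0.3214002 0.01621133 0.01656130
#> seed_viability seed_viability  7 0.3826262 0.01309668 0.01337941
attr(ct, "T")
#> [1] 0.9788683
```

Pre-zygotic isolation contributes most (AC 0.80 of a total T ≈ 0.98); each
later stage can only remove gene flow the earlier stages let through. Note
`n` drops from 15 to 7: pairs setting no fruit in either direction cannot be
assessed at the later post-zygotic stages.

```r
gmf <- filter_sites(sim$gm)                # depth>=10, no missing, het<=0.8, 20 bp
dm  <- nei_distance(gmf)
bt  <- bootstrap_tree(gmf, n_reps = 1000, seed = 7)
ape::write.tree(bt$tree)
#> ((sp01:0.146,sp02:0.134)100:0.140,sp03:0.125,(sp06:0.117,(sp04:0.105,sp05:0.111)100:0.169)100:0.292);

mantel(ri_matrix(summ, "pollen_pistil"), dm, n_perm = 9999, seed = 7)$p_value
#> [1] 0.0076
```

The generating topology is recovered with 100% bootstrap support and the
pollen-pistil RI matrix correlates with genetic distance (Mantel one-sided
p = 0.0076), the positive isolation–distance relationship the generator
encodes.

A command-line interface wraps the same steps
(`simulate`, `crosses`, `ri`, `contributions`, `geneaction`, `filter`,
`distance`, `tree`, `mantel`, `heatmap`, `run`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "crossiso.R", package = "crossiso"))')
Rscript "$CLI" simulate --seed 7 --out simdata
Rscript "$CLI" run --crosses simdata/crosses.tsv --vcf simdata/genotypes.vcf \
  --out results --seed 7
```

Exit codes: 0 success, 2 validation error, 3 stage failure. Outputs are TSV
tables, Newick trees, and a JSON manifest recording the seed and per-step
filter counts.

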