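# coexdriver

Prioritize candidate cancer driver genes by integrating tumor/normal
expression, somatic mutations, and copy-number alterations on a
protein–protein interaction (PPI) network.

Frequency-based driver detection misses rarely mutated drivers and is
biased toward long genes whose high mutation counts are artifacts. This
package implements an integrative alternative built on the idea that a
driver reveals itself through its *neighbors*: its aberration rewires the
coexpression of its network links and impinges on the functional genes it
touches.

For each gene $g$ with network links $1,\dots,n_g$, the change in link
correlations between conditions is summarized by

$$dC(g)=\sqrt{\tfrac{1}{n_g}\textstyle\sum_j\big(r_j^{tumor}-r_j^{normal}\big)^2},$$

tested against a tumor/normal label-permutation null and selected at
BH FDR < 0.25 (the *differentially coexpressed genes*, DCGs). Each DCG's
impact on the functional gene sets (e.g. KEGG pathways + tumor-hallmark GO
terms) is its summed $|PCC|$-weighted bipartite connectivity $d_{AF}$,
standardized against a resampled functional-gene null:

$$z_{dcg}=\frac{d_{AF}-\mu_{AF}}{\sigma_{AF}}.$$

Adding the standardized alteration recurrence $z_{mut}$ (SNVs plus GISTIC
high-level calls) gives the **driver gene score** $z_{dcg}+z_{mut}$;
genes scoring ≥ 2 are candidate drivers, and top-30 candidates altered in
< 2% of tumors and absent from the benchmark list are flagged as *rare
drivers*. MCODE-style dense-module detection and local hypergeometric
gene-set enrichment annotate the result.

A seeded synthetic-data generator (scale-free network, latent-factor
expression with planted coexpression rewiring, recurrent driver mutations,
a highly mutated "long-gene" decoy) makes the entire pipeline testable
with no downloads.

## Worked example

```r
library(coexdriver)

sim <- simulate_dataset(simulation_config(seed = 1))
#> <sim_data> 500 genes, 60 tumor / 30 normal samples, 10 planted drivers, decoy G0195

res <- prioritize_drivers(
  sim$expression, sim$mutations, sim$network, sim$gene_sets,
  benchmark = sim$benchmark, n_perm = 199, n_null = 100, seed = 2
)

head(tidy(res$drivers), 5)
#>   gene   rank  z_dcg z_mut driver_score n_mutated alteration_fraction
#> 1 G0105     1  1.81   5.09         6.90        19               0.317
#> 2 G0185     2  2.10   3.95         6.05        15               0.25
#> 3 G0168     3  1.06   4.81         5.87        18               0.3
#> 4 G0087     4 -0.270  5.66         5.39        21               0.35
#> 5 G0288     5  0.649  4.52         5.17        17               0.283

glance(res$dcg)
#>   n_genes n_dcgs min_q n_perm fdr_threshold n_tumor n_normal
#> 1     500     44   0.1    199          0.25      60       30

as.data.frame(res$curve)
#>    k cumulative_hits precision recall        f1
#> 1 10              10       1.0      1 1.0000000
#> 2 25              10       0.4      1 0.5714286
```

All ten planted drivers are recovered in the top 10 (`precision = 1` at
`k = 10`), while the decoy gene `G0195` — mutated in ~90% of tumors but
with no coexpression rewiring and no functional-gene neighbors — is not
nominated at all: it never passes the DCG gate, so its mutation count
alone cannot carry it into the ranking. `res$overlap_p` (~4e-21 here) is
the hypergeometric probability of the candidate/benchmark overlap arising
by chance.

`autoplot()` methods are provided for the DCG table, the driver table and
the evaluation curve; `tidy()`/`glance()` follow broom conventions.

## Command line

A thin CLI over the same functions ships in `inst/cli/`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/coexdriver", package = "coexdriver"))')
Rscript $CLI simulate --out bundle/ --seed 1
Rscript $CLI run --expression bundle/expression.tsv --conditions bundle/conditions.tsv \
    --maf bundle/mutations.maf --network bundle/network.sif \
    --gene-sets bundle/gene_sets.gmt --gistic bundle/cnv_gistic.tsv \
    --benchmark bundle/benchmark.txt --out run/ --seed 2
Rscript $CLI evaluate --drivers run/drivers.tsv --benchmark bundle/benchmark.txt --out curve.tsv
```

Inputs are plain TSV/SIF/GMT/MAF-like text files; `run/` receives the
ranked driver table, DCG table, evaluation curve, module memberships,
enrichment table, and a JSON manifest that records every parameter and
seed needed to reproduce the run exactly.

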