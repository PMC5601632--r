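---
title: "Prioritizing cancer driver genes from differential coexpression and network impact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing cancer driver genes from differential coexpression and network impact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexdriver)
```

## The model

Driver genes confer a selective advantage to a tumor; passengers merely ride
along. Frequency-based driver detection misses rare drivers and is biased
toward long genes, whose high mutation counts are often artifacts. This
package ranks candidate drivers by combining two orthogonal signals on a
protein-protein interaction (PPI) network:

1. **Differential coexpression.** In a biological network an interacting
   gene pair tends to be correlated; a driver's aberration perturbs those
   correlations. For every gene $g$ with network links
   $1, \dots, n_g$ we compute the Pearson correlation of each link
   separately in tumor and normal samples and summarize the change with the
   root-mean-square statistic
   $$dC(g) = \sqrt{\frac{\sum_{j=1}^{n_g}\left(r^{\mathrm{tumor}}_j -
   r^{\mathrm{normal}}_j\right)^2}{n_g}} \in [0, 2].$$
   Significance comes from a label-permutation null: tumor/normal labels
   are shuffled globally (group sizes preserved), every edge correlation
   and every $dC$ recomputed per shuffle, and
   $p(g) = \bigl(1 + \#\{dC^{\mathrm{perm}} \ge dC^{\mathrm{obs}}\}\bigr) /
   (n_{\mathrm{perm}} + 1)$. Benjamini–Hochberg adjustment across genes and
   a q-value threshold (default $q < 0.25$) select the differentially
   coexpressed genes (DCGs).

2. **Network impact of a DCG on functional genes.** Curated gene sets
   (e.g. KEGG pathways plus tumor-hallmark GO terms) define the
   *functional genes*. A bipartite graph links each DCG to the functional
   genes it touches in the PPI network, each edge weighted by the tumor
   coexpression magnitude $|r|$. A DCG's impact is
   $d_{AF}(g) = \sum_{f} w(g, f)$, and its z-score
   $z_{\mathrm{dcg}} = (d_{AF} - \mu_{AF}) / \sigma_{AF}$ is taken against
   a Monte-Carlo null in which the functional-gene label set is replaced by
   a uniformly random node set of the same size ($n_{\mathrm{null}}$ draws;
   sample standard deviation).

3. **Mutation recurrence.** Somatic mutations and thresholded gene-level
   copy-number calls are combined into a binary gene × sample alteration
   matrix ($|$call$| \ge 2$ by default, i.e. high-level amplification or
   deep deletion); per-gene counts are standardized over all genes in the
   matrix to give $z_{\mathrm{mut}}$.

The **driver gene score** of a candidate is
$z_{\mathrm{dcg}} + z_{\mathrm{mut}}$ (a missing component contributes 0),
genes with score $\ge 2$ are nominated as candidate drivers, and a
candidate is flagged a **rare driver** when it ranks in the top 30, is
altered in fewer than 2% of tumor samples, and is absent from the
benchmark list of known drivers.

## Design decisions

Several aspects of this construction were genuinely open; the choices made
here are deliberate and exposed as parameters where reasonable.

**Candidate universe.** The ranked table is restricted to DCGs by default
(`candidates = "dcg"` in `driver_scores()`). Admitting every mutated
network gene (available as `candidates = "dcg_or_mutated"`) would let a
recurrently mutated gene with no coexpression disruption — the long-gene
artifact pattern — dominate the list on its mutation z-score alone, which
is precisely the failure mode the integrative score exists to avoid. The
DCG gate is what gives the method its robustness to such genes: a gene
whose correlations do not change between conditions is never scored,
however often it is mutated.

**A gene's links.** The DCp statistic is computed over a gene's PPI
neighbors present in the expression matrix, not over all-pairs
coexpression screens. This keeps the statistic aligned with the downstream
bipartite scoring (both live on the same network) and costs
$O(\mathrm{edges})$ per permutation.

**Permutation scheme.** Labels are shuffled once per round and all edges
recomputed under that single shuffle, preserving the cross-gene
correlation of the null; the add-one p-value formula keeps $p > 0$ so BH
adjustment is well defined.

**Bipartite edge weights.** The default weight is $|r|$ over tumor samples
(`weight_mode = "abs_tumor"`): strong negative coexpression is still
influence. Signed and normal-condition variants are available.

**Impact null.** The null randomizes the functional-gene *labels* rather
than rewiring the graph: topology and weights stay fixed, draws are cheap,
and the test asks exactly "is this DCG unusually connected to *these*
genes rather than to an arbitrary same-sized set?". Degree-preserving edge
rewiring would be the natural alternative but conflates topology
uncertainty with label enrichment. A degenerate null
($\sigma_{AF} = 0$) yields $z_{\mathrm{dcg}} = 0$, flagged.

**Ties.** Ranking ties on the driver score are broken by higher alteration
count, then lexicographic gene symbol, making output deterministic.

**Enrichment and modules.** Gene-set enrichment is a local upper-tail
hypergeometric test (computed via `phyper`, i.e. in log space) with BH
adjustment and a q < 0.05 flag, against a configurable background
(defaulting to the network nodes). Dense modules in the neighborhood of
the top 50 drivers are found with an MCODE-style procedure: vertices are
weighted by (highest k-core of the closed neighborhood) × (density of that
core), complexes grow greedily from the heaviest unvisited seed admitting
neighbors above `seed weight × (1 − vwp)` (`vwp = 0.2`), and each complex
is reduced to its 2-core and split into connected components. Reducing to
the core (rather than merely requiring one to exist) guarantees every
reported module has minimum degree ≥ 2 and is connected. Haircut/fluff
post-processing options are deliberately omitted.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_perm` | 199 | label permutations for the DCp p-value (floor $1/200$) |
| `fdr_threshold` | 0.25 | q-value cutoff defining DCGs |
| `n_null` | 100 | Monte-Carlo draws of the impact null |
| `score_threshold` | 2 | driver-score cutoff for candidate drivers |
| `cnv_threshold` | 2 | min \|GISTIC call\| counted as an alteration (1 admits gains/losses) |
| `weight_mode` | `"abs_tumor"` | bipartite edge weighting |
| `candidates` | `"dcg"` | candidate universe (see above) |
| `rank_cutoff`, `freq_cutoff` | 30, 0.02 | rare-driver criteria |
| `mcode_k_core`, `mcode_vwp` | 2, 0.2 | module detection |
| `enrich_alpha` | 0.05 | enrichment significance on the q-value |

All randomness in a pipeline run derives from one `seed`; identical seeds
give byte-identical output files at the written precision (6 decimals).

## The synthetic testbed

Real cohorts (hundreds of tumors, curated PPI networks, benchmark driver
lists) cannot ship with a package, so `simulate_dataset()` generates a
complete input bundle with the statistical structure the method assumes:

* **Network** — preferential attachment (2 edges per node), giving a
  connected scale-free graph of 500 genes by default with
  $2(n-2)$ edges.
* **Expression** — a latent node-factor model: each gene carries its own
  standard-normal factor, and adjacent genes load on each other's factors
  through a per-edge coupling ($b = 2$), plus unit-variance noise. The
  own-factor weight $a$ is solved so a degree-2/degree-2 edge would have
  Pearson correlation $\rho = 0.6$; realized edge correlations attenuate
  with endpoint degree (hubs pool many factors), spanning roughly 0.1–0.55
  as in real coexpression data. 60 tumor and 30 normal samples are drawn
  by default — a desk-scale version of typical tumor/normal cohort ratios.
* **Rewiring** — each edge incident to one of the 10 planted drivers has
  its coupling flipped in sign (4:1 odds) or silenced, independently with
  probability $\delta = 0.8$, in tumors only. Sign reversal is the
  canonical differential-coexpression pattern; silencing is kept as a
  minority mode. Drivers are planted on moderate-degree nodes (3–6) with
  at least a couple of low-degree partners, because under any
  variance-bounded latent model a hub's per-edge correlation is too
  attenuated to carry a rewiring signal — real hub drivers would be
  detected through larger cohorts, not through this testbed.
* **Mutations** — planted drivers mutate per tumor sample with frequency
  0.3 over a 1% passenger floor; all 500 genes form the matrix.
* **Functional gene sets** — 15 sets of 10–30 genes sampled so that about
  half of each planted driver's eligible neighbors (always ≥ 1) are in the
  union, while the decoy and its neighbors are excluded.
* **Decoy** — one non-planted gene, two hops away from every planted
  driver, mutated at 3× the driver frequency but with no rewiring and no
  functional-gene adjacency: the long-gene artifact in miniature. A
  correct integrative ranking keeps it out of the top 10.

What the generator does **not** emulate: TCGA marginal expression
distributions, mutational signatures, copy-number segment structure,
patient-specific networks, or hub drivers. Passing the planted-recovery
tests therefore shows the pipeline correctly exploits the assumed
signal structure — not that it would attain any particular accuracy on a
real cohort.

## Numerical choices and degenerate inputs

* Constant-expression genes get a defined edge correlation of 0 and are
  flagged rather than propagating `NaN`.
* Row-standardization to unit norm turns each edge correlation into a dot
  product, so a permutation round costs one pass over the matrix plus one
  over the edges.
* `p.adjust(method = "BH")` performs the step-up adjustment;
  permutation p-values are bounded below by the add-one formula, never 0.
* All-equal mutation counts give $z_{\mathrm{mut}} = 0$ for every gene
  (flagged), as does a degenerate impact null.
* Missing expression cells must be imputed (gene-mean, tumor and normal
  pooled) before correlation; a gene with no present values is a hard
  error. Per-condition imputation was considered and rejected as it leaks
  condition identity into the correlation estimates.
* Writers emit numerics with 6 decimals so re-reading reproduces tables
  exactly at the written precision and identical runs produce
  byte-identical files.

## Problem sizes used by the test suite

The shipped tests run the full pipeline at the reference conditions
(500 genes, 60 + 30 samples, 99 permutations for the recovery and decoy
checks) and at reduced sizes (150–250 genes, 20–50 samples, 19–49
permutations) for unit and property checks; the permutation test's null
calibration is verified on a 200-gene, 30 + 30-sample dataset with no
rewiring at 199 permutations. These sizes are the package's reference
configuration for a laptop-scale, seconds-to-minutes test cycle.

At small scales (or unlucky draws) it can happen that no gene clears the
DCG threshold; the pipeline then stops with an explicit error rather than
silently ranking on mutation counts alone.

## Known limitations

* The network is global, not patient- or cancer-type-specific; perturbations
  private to a patient are invisible.
* DCGs and functional genes absent from the PPI network are dropped (and
  reported), so coverage of the interaction database bounds recall.
* The method assumes drivers act through coexpression disruption of their
  neighbors; drivers without such a footprint are missed by design of the
  DCG gate.
* The mutation z-score treats all alteration types equally; no
  variant-level functional impact is modeled.

## A minimal session

```{r example, eval = FALSE}
library(coexdriver)

sim <- simulate_dataset(simulation_config(seed = 1))
res <- prioritize_drivers(
  sim$expression, sim$mutations, sim$network, sim$gene_sets,
  benchmark = sim$benchmark, seed = 2
)
head(tidy(res$drivers))
glance(res$dcg)
autoplot(res$curve)
```
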