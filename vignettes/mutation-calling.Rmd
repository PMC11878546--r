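---
title: "Calling lineage-informative mitochondrial mutations with mitocall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling lineage-informative mitochondrial mutations with mitocall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocall)
```

## The problem

Mitochondrial DNA accumulates somatic mutations fast enough, and is present
in enough copies per cell, that mutations shared between single cells mark
common ancestry. In scATAC-seq and single-cell genome sequencing, mtDNA reads
come for free, so a per-cell, per-locus read count table over the four bases
is available for the whole mitochondrial genome. The difficulty is deciding,
cell by cell, whether a reduced count of the majority allele reflects a real
heteroplasmic mutation or just sampling noise: a fixed allele-frequency
cut-off ignores that a 20% minor fraction at depth 5 is one read while the
same fraction at depth 500 is a hundred reads. `mitocall` replaces the
cut-off with a hypothesis test calibrated per locus.

## The model

For cell $i$ and locus $j$, the counts of A, T, C and G sum to the depth
$N_{i,j}$. The wild-type (WT) allele of a locus is defined without a
reference genome as the base whose **median raw count across cells** is
largest; this makes individual germline polymorphisms invisible to the
caller, which is what one wants for lineage tracing. Writing $m_{i,j}$ for
the WT-allele count, $\mathrm{wAF}_{i,j} = m_{i,j}/N_{i,j}$ is the observed
WT allele frequency and a proxy for the cell's WT heteroplasmy.

Sequencing a cell's mtDNA pool is modelled as Bernoulli sampling, so the WT
count at one locus is binomial given the cell's heteroplasmy $\pi$.
Heteroplasmy itself varies between cells (mitochondrial turnover, drift), so
$\pi$ is treated as a Beta random variable, giving a beta-binomial null

$$X \sim \mathrm{BBD}(N, \alpha, \beta), \qquad
\theta = \frac{\alpha}{\alpha+\beta}, \quad
\phi = \frac{1}{\alpha+\beta+1},$$

with mean $\theta$ and dispersion $\phi$; at $\phi = 0$ the model reduces to
the binomial. A mutation in cell $i$ shows up as a WT count in the lower
tail of this null, so the test is one-sided ($H_1: \pi_i < \theta$) with

$$P_{\mathrm{BBD}} = P(X \le m_i \mid N_i, \alpha, \beta),$$

adjusted across the cells of each locus by Benjamini–Hochberg; the adjusted
value is the **mutation q-value**. Only loss of the WT allele is tested:
under realistic mutation loads, two different mutant alleles at the same
locus are vanishingly rare (see the collision simulation below), so each
locus is treated as WT-or-one-mutation.

### Wild-type cell preselection

Fitting the null on all cells would let a sizeable mutant clone inflate the
fitted variance and mask itself. Before the beta-binomial fit, a
two-component binomial mixture

$$X \sim \theta_W \, B(N, \pi_W) + \theta_M \, B(N, \pi_M)$$

is fitted per locus by EM, and cells whose WT-component lower-tail
probability (BH-adjusted across the locus) exceeds 0.05 are kept as the WT
reference set. The mixture deliberately allows no within-population
heteroplasmy variation — that rigidity is what makes it a robust
preselector rather than a final model. Preselection can be disabled
(`preselect = FALSE`), and if fewer than two cells survive it, all cells are
used with a warning.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `q_threshold` | 0.01 | per-cell mutation q-value below which a cell counts as mutant |
| `min_mutant_cells` | 5 | minimum mutant cells for a locus to be reported (10 is a sensible choice for sparse multiome data) |
| `min_mean_depth` | 5 | per-cell mean mtDNA depth required to enter fitting (strictly greater); `depth_stat = "median"` is available |
| `classifier_fdr` | 0.05 | adjusted-P threshold of the WT preselection |
| `preselect` | TRUE | whether to preselect WT reference cells |

The q-value threshold is the parameter that actually moves precision;
the others mainly trade off how many loci are examined.

## A worked example

```{r example}
clones <- c(rep("clone1", 20), rep("bulk", 180))
spec <- clone_sim_spec(
  n_cells = 200, n_loci = 30, clones = clones,
  planted = data.frame(locus = 5L, clone = "clone1", het = 0.7),
  depth_meanlog = log(50), depth_sdlog = 0.3, seed = 42
)
sim <- simulate_dataset(spec)
calls <- fit_all_loci(sim$tensor)
mset <- call_mutations(calls)
mset$mutations
```

The planted locus (`chrM.150`, 20 cells at mutant heteroplasmy 0.7) is the
only reported mutation. Precision against the known clone:

```{r precision}
labels <- setNames(sim$truth$clones == "clone1", names(sim$truth$clones))
mutation_precision(mset, labels)$per_mutation
```

Downstream, `celltype_frequency()` and `cluster_celltypes()` group cell
types by shared mutations (complete-linkage clustering on Euclidean
distances between normalized mutant-count profiles), and `memo_sort()`
orders a binary mutation-by-cell matrix into the staircase layout used for
clonal heatmaps.

## The synthetic data generator

`clone_sim_spec()`/`simulate_dataset()` generate data with exactly the
structure the model assumes: per cell and locus, heteroplasmy is drawn from
a Beta law with locus mean $\theta$ and precision $s = \alpha + \beta$,
depth from a log-normal law rounded **up** to an integer, and the WT count
binomially; all non-WT reads go to one fixed alternative base per locus.
Defaults follow the conditions used for the model-recovery benchmarks:
log-normal depth with log-mean 2 and log-SD 1 (median depth about 7, as in
typical mtDNA-containing scATAC data), baseline WT heteroplasmy 0.999 with
precision 100 (occasional sub-0.99 cells, matching the heavy lower tail
real loci show), and 200 cells. Planted clones override the heteroplasmy of
chosen (locus, clone) pairs.

Because the generator *is* the model, passing recovery tests shows the
estimators and the calling logic are correct, not that real data satisfy
the model: real scATAC counts add strand asymmetries, alignment artefacts,
RNA contamination and position-dependent coverage that the generator does
not emulate. Those effects are exactly why upstream QC (depth filtering,
DNA-based inputs) remains necessary.

A second generator, `collision_spec()`/`collision_probability()`, checks
the one-mutation-per-locus assumption: all $16{,}000 \times 3 = 48{,}000$
possible single-nucleotide events on a 16 kb genome are enumerated, 50
mutations are drawn without replacement per repetition, and the fraction of
drawn mutations that share a locus with another drawn mutation is averaged
over repetitions. The estimate agrees with the closed-form pair-collision
expectation $(k-1)/(E-1) \approx 0.00102$, i.e. about one in a thousand —
small enough to justify the assumption at current mutation loads.

## Numerical choices

* **Binomial-mixture EM** starts the two component probabilities at the
  10th and 90th percentiles of observed wAF with equal weights. When both
  percentiles coincide (heavily skewed data, e.g. a small mutant fraction),
  that start is a symmetric saddle from which EM cannot escape, so the
  second component instead starts at the mean of the below-maximum wAF
  values. Convergence is declared at a relative log-likelihood change below
  1e-8 (at most 500 iterations); components are relabeled so the WT
  component is the high-probability one. The one-point case (all cells at
  the same wAF, e.g. fully saturated loci) returns a flagged degenerate
  fit instead of iterating.
* **Beta-binomial MLE** maximises the exact log-likelihood via log-beta
  functions, parameterised as $(\mathrm{logit}\,\theta, \log s)$. These are
  the natural axes of the problem — the mean is sharply identified, the
  precision weakly — whereas $(\log\alpha, \log\beta)$ has a curved ridge
  on which quasi-Newton line searches stall. Optimisation starts from a
  method-of-moments estimate plus a second moderate-precision start
  ($s = 20$) that guards against the moment estimate landing on the flat
  near-binomial plateau; the better optimum wins. Precision is capped at
  $10^8$, where the model equals the binomial to numerical accuracy.
* **Saturated reference sets.** When the preselected reference cells carry
  no mutant reads at all (common at high depth when heteroplasmy is near
  1), $\hat\theta$ sits on the boundary and every tail probability would
  collapse to zero, flagging any cell with a single stray read. The fit
  then returns the capped-precision binomial with the continuity-corrected
  mean $(\sum m + 0.5)/(\sum N + 1)$, so the evidence threshold scales with
  the total reference read count.
* **Tails are inclusive**, $P(X \le m)$, for both the classifier and the
  beta-binomial test. The difference from the strict tail is one pmf term;
  the inclusive version is the conservative choice (it can only make
  q-values larger) and is used consistently.
* **Ties** in the WT-allele medians are broken toward the earlier base in
  A < C < G < T and flagged. Medians over an even number of cells are the
  midpoint of the central order statistics. Cells with zero depth at a
  locus get missing (`NA`) wAF, p and q — never 0 or 1.
* **BH adjustment** is computed over the cells actually tested at a locus
  (zero-depth cells are not tests) and never pooled across loci.

## Design choices that were genuinely open

* The WT allele is computed from **all imported cells**; the depth filter
  applies only to model fitting and calling. A locus' identity should not
  depend on which cells pass QC.
* The depth law rounds **up** (ceiling), following the benchmark
  description of the simulated depth distribution; this also guarantees a
  positive depth for every simulated cell, with zero-depth handling
  exercised separately.
* The per-locus loop parallelises with forked workers, and contains no
  randomness, so results are bit-identical for any worker count.
* Results persist in a directory-backed hierarchical store (groups
  `counts`, `wildtype`, `bm_fit`, `bb_fit`, `pvals`, `calls`; RDS datasets
  with JSON attribute sidecars). Re-calling with new thresholds via
  `call_mutations(store_open(path), config)` reuses persisted fits without
  refitting.
* At least two usable reference cells are required per locus; loci below
  that are flagged (`status`) and skipped rather than failing the run.

The recovery test suite uses 5000-observation simulations per setting
(20 seeds per grid point for the EM and MLE accuracy grids) and 200-locus,
200-cell datasets for the end-to-end and false-call-rate checks.

## Known limitations

* One mutation per locus: a locus genuinely carrying two mutant alleles
  would have its minor allele misattributed. At ~50 detected mutations per
  dataset the collision probability is ~0.001, but deeper mutation
  detection would require revisiting this.
* The binomial-mixture classifier assumes exactly two populations; loci
  with several clones at distinct heteroplasmies are still preselected
  sensibly (everything below the WT bulk is excluded) but the fitted
  mixture parameters should not be over-interpreted.
* RNA-based inputs are not supported by design; RNA editing would be called
  as mutation. DNA-derived counts (scATAC, scDNA) are the intended input.
* The AD/DP import dialect is biallelic by construction; truly
  multi-allelic loci must come through the per-base dialect.
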