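---
title: "Mining coexpression networks for biosynthetic gene clusters: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining coexpression networks for biosynthetic gene clusters: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcoex)
library(SummarizedExperiment)
```

## The problem

Fungal secondary metabolites are encoded by biosynthetic gene clusters
(BGCs): contiguous genomic blocks holding a core synthase (PKS, NRPS, FAS,
terpene cyclase), tailoring enzymes, transporters and sometimes a resident
transcription factor (TF). Most BGCs are transcriptionally silent under
routine laboratory conditions, and their regulators — especially global
regulators — often sit outside the cluster. Given a large expression
compendium spanning many cultivation conditions, guilt-by-association can
recover both the cluster boundaries and candidate regulators: genes of one
pathway tend to be switched on together.

`mrcoex` implements that analysis as a pipeline of small, testable stages:

1. cross-experiment scaling of an intensity matrix to a common trimmed mean;
2. two complementary coexpression networks — a Spearman (SCC) network and a
   mutual-rank transformed Pearson (MR-PCC) network family;
3. overlapping module detection by greedy cohesiveness optimization;
4. collapse of the modules around genes of interest into a metamodule;
5. per-BGC and per-TF coexpression reporting and TF shortlisting.

Because public compendia of this kind are not always obtainable, the package
ships a synthetic-compendium generator with planted structure; every claim
the package makes about itself is tested against that ground truth.

## Models and statistics

### Cross-experiment scaling

Arrays from different experiments sit on different intensity scales. Each
sample column $j$ is multiplied by $T/t_j$, where $t_j$ is the column's
trimmed mean (per-tail trim fraction 0.05 by default, with the deterministic
rule of dropping exactly $\lfloor 0.05\,n \rfloor$ values per tail) and the
cross-experiment target $T$ is the mean of the per-column trimmed means.
With this definition of $T$ the operation has two exact properties that make
it safe to apply blindly: it is the identity when all columns already share
one trimmed mean, and it is idempotent. A pooled-matrix trimmed mean was
considered for $T$ and rejected: pooling mixes within-array and
between-array variation, and the resulting transform is no longer an exact
fixed point.

### Mutual rank and decay weights

Pearson correlations are computed between every pair of genes, each gene's
partners are sorted from most to least correlated (ties broken by ascending
gene id so results are reproducible), and each pair is scored by the
geometric mean of the two reciprocal list positions:

$$\mathrm{MR}(A,B) = \sqrt{\mathrm{Rank}_A(B)\cdot \mathrm{Rank}_B(A)}.$$

Mutual best partners attain the minimum $\mathrm{MR}=1$. The appeal for
rarely expressed genes is that MR is a *relative* statistic: a sparse gene
may carry inflated raw correlations with many other sparse genes, but only
its genuinely co-regulated partners rank it highly *and* are ranked highly
by it.

MR scores become edge weights through the exponential decay
$w = e^{-(\mathrm{MR}-1)/x}$, so $w(1) = 1$ for every $x$ and $w$ falls off
at a speed set by $x$. Three networks are built at $x = 5, 10, 25$
(NET05, NET10, NET25 — stringent to relaxed). An edge is kept iff the signed
Pearson correlation is at least 0.3 *and* the weight is at least 0.1; the
weight threshold therefore corresponds to the analytic MR cutoffs
$1 + x\ln 10 \approx 12.5,\ 24.0,\ 58.6$. Because the PCC filter does not
depend on $x$, the three edge sets are provably nested,
$\mathrm{NET05} \subseteq \mathrm{NET10} \subseteq \mathrm{NET25}$, which the
tests assert. The PCC filter is applied to the signed coefficient (a
configuration flag allows the absolute-value reading); negative
correlations never enter MR networks. Ranks are computed over all genes and
the PCC mask is applied only at edge assembly.

The SCC network keeps an edge where $|\rho| \ge 0.5$ (Spearman with average
ranks for ties), recording the signed $\rho$ and using $|\rho|$ as the
weight. Spearman is invariant under strictly monotone per-gene transforms, a
property the tests verify on transformed copies of one matrix.

### Overlapping modules by cohesiveness

Module detection re-implements greedy cohesiveness clustering. The
cohesiveness of a gene set $V$ is

$$f(V) = \frac{w_{in}}{w_{in} + w_{bound} + p\,|V|},$$

with $w_{in}$ the total weight of edges inside $V$, $w_{bound}$ the total
weight of edges crossing the boundary, and a per-node penalty $p$ (default
2) modelling unobserved connections. Growth starts from a seed gene and
repeatedly applies the single best strictly-improving move — adding an
external node incident to the set or removing an internal node — until the
set is locally optimal; ties between moves are broken by ascending gene id.
Seeds are taken in decreasing weighted-degree order among nodes not yet
covered by a grown module (an every-node seeding mode is available). Grown
sets smaller than 3 genes or with weighted density
$2 w_{in} / (|V|\,(|V|-1))$ below 0.3 are discarded; remaining sets with
overlap score $\omega(A,B) = |A\cap B|^2/(|A||B|) \ge 0.8$ are merged
transitively (the merge graph's connected components are unioned, which
makes merging order-independent). Modules may overlap: a gene — typically a
regulator — can belong to several modules. The clusterer's significance
p-value from the original algorithm is deliberately not implemented; module
quality is reported as cohesiveness plus density, which is what the
downstream reporting uses.

On graphs small enough for exhaustive search, the tests enumerate *all*
connected, locally optimal, filter-passing sets and check that every
emitted module belongs to that family and verifies single-move local
optimality. Note that the family itself can be larger than what seeded
greedy growth emits (e.g. the union of two bridged cliques can also be
locally optimal); the procedure's contract is soundness of every emitted
module plus exact recovery of the prototype structures, not enumeration of
every local optimum.

### Metamodules and reporting

For genes of interest (e.g. a pair of cluster-resident TFs), all modules
from any supplied network that contain at least one anchor are collapsed
into a single non-overlapping gene set, recording the contributing modules.
Per BGC, the report counts member genes recovered in any module and flags
the BGC as coexpressed iff at least two members share a module (both the
gene-recovery count and the shared-module flag are emitted, since either
reading of "recovered" may be wanted). Per TF, two counts are computed:
the SCC rule counts catalog core genes directly adjacent to the TF in the
Spearman network (1-hop; component membership would not discriminate at
these thresholds, since the largest SCC component spans hundreds of genes),
and the MR rule counts core genes sharing at least one module with the TF.
A TF is shortlisted as a putative *global* regulator when its SCC count
reaches 10, and as a putative *pathway-specific* regulator when its shared
modules contain core genes of at least two distinct BGCs; each entry is
labelled clustered/unclustered from the catalog.

## The synthetic compendium

The generator plants known structure in an otherwise unstructured matrix so
that recovery can be measured exactly.

* **Signal model.** Independent Gaussian intensities per (gene, sample) on a
  log-like scale, clipped at zero; baseline $\mathcal N(4, 0.5^2)$, planted
  groups at $\mathcal N(10, 0.5^2)$ (scenario rare clusters at 13, since
  rarely expressed secondary-metabolism genes are strongly induced when they
  fire). The downstream methods are rank- and correlation-based, so
  distributional shape beyond the on/off contrast is secondary. One
  consequence worth knowing: Spearman correlation between two on/off genes
  sharing an active window saturates well below 1 and grows with the active
  fraction, so $|\rho| \ge 0.5$ edges require windows of roughly 45+ of 155
  conditions. That is a faithful property of threshold-style expression, not
  an artifact.
* **Groups.** Planted co-regulated groups occupy contiguous gene ids
  (BGC-like genomic contiguity) and explicit or randomly drawn
  active-condition windows.
* **Regulators.** A regulator's profile is the mean of its target groups'
  ideal profiles plus Gaussian noise, which makes regulator-target
  coexpression recoverable by construction. Coexpression at $\rho \ge 0.5$
  additionally requires the targets to be genuinely co-active, so the
  reference compendium's global TF drives one fully co-active 20-gene
  regulon that the genomic catalog splits into two contiguous BGCs of six
  core genes each — the unclustered-TF-with-many-cores pattern.
* **Confounders.** Sparse confounders are at baseline except for their
  hosting group's aberrant conditions: three drawn inside the group's
  active window (producing spurious $|r| \ge 0.5$ with every group member
  under plain correlation) and two outside every window (where only the
  confounders fire). Confounders are assigned to hosting groups round-robin
  so the sparse-gene crowds stay balanced. The shared conditions are the
  point: in real compendia rarely expressed genes correlate spuriously with
  *each other* because they respond to the same few odd conditions, and it
  is exactly this crowd that pushes a confounder's mutual ranks with genuine
  cluster members down. With isolated, per-gene-random spikes the
  confounder correlates with the whole group and with nothing else — such a
  gene is indistinguishable from a weakly expressed member, no rank
  statistic can exclude it, and early versions of the generator confirmed
  that the clusterer (correctly) absorbs it.
* **Reference designs.** `rareClusterScenario()`: 400 genes, 155
  conditions, three rare groups (10, 8, 8 genes active in 5, 5, 4
  conditions) and 75 confounders. `plantedCompendium()`: 1,000 genes, 155
  conditions, seven groups (12, 12, 20, 8 frequently expressed; 12, 12, 11
  rarely expressed), a resident TF pair jointly tracking the two partially
  co-active anchor groups, the global-TF regulon described above, 60
  confounders on the rare windows, and three silent BGCs whose genes never
  leave baseline. These sizes keep the full pipeline under ten seconds on
  one CPU while leaving every effect measurably above noise.

What passing tests on this generator do **not** show: robustness to batch
effects, missing values, probe-level artifacts, graded (non-switch-like)
expression, or correlated noise across genes — none of which the generator
emulates. Results on real compendia depend on upstream normalization
quality in ways the synthetic tests cannot certify.

## Numerical choices

* Trim counts use `floor(trim * n)` per tail; no interpolation.
* Rank ties break by ascending gene id; Spearman uses average ranks.
* Greedy growth accepts a move only if it improves cohesiveness by more
  than $10^{-12}$ (guards against floating-point cycling); move ties break
  by ascending gene id, so detection is deterministic.
* Zero-variance genes must be dropped explicitly
  (`dropZeroVarianceGenes()`, which warns with the dropped ids) before
  correlation.
* Edge weights are kept at full precision in memory; TSV export rounds to 6
  decimals, and all writers omit timestamps so fixed-seed reruns are
  byte-identical.
* All randomness flows from one seeded generator per simulation call, and
  the caller's global RNG state is restored afterwards.

## Open design points resolved here

* The compendium's condition composition is not prescribed anywhere;
  the reference designs above are this package's own and are frozen as the
  study conditions its acceptance checks run under.
* Whether the trimmed-mean target pools all values or averages per-array
  trimmed means: per-array averaging chosen (see above).
* Whether the PCC $\ge 0.3$ filter is signed or absolute: signed by
  default, configurable.
* Whether metamodule collapse pools all networks or a subset: the function
  takes an explicit list of module sets; the pipeline passes all three MR
  networks.
* Module-detection defaults (minimum size 3, minimum density 0.3, penalty
  2, merge overlap 0.8) follow the published defaults of the cohesiveness
  clusterer this stage re-implements; all are arguments.

## Known limitations

* The greedy clusterer commits to the single best move; it can stop at a
  local optimum that exhaustive search would extend (tested behavior, see
  above).
* SCC-based TF counts use direct edges only; a regulator correlated with a
  pathway just below $|\rho| = 0.5$ contributes nothing.
* The generator's on/off expression model understates Spearman
  correlations relative to graded co-expression (see above); thresholds
  tuned on it should be revalidated on real data.
* Catalog coordinates are carried and validated (1-based, inclusive) but no
  positional analysis is performed beyond bookkeeping.
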