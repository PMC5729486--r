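---
title: "Anatomical network analysis of the mammalian neck: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomical network analysis of the mammalian neck: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(necknet)
```

This vignette is the package's own account of the science it implements:
the network model of the neck, the statistics computed on it, the choices
made where conventions were genuinely open, and what the synthetic-data
generator does and does not establish.

## The network model

A species' neck is modelled as a simple undirected graph. Nodes are the
anatomical elements involved in head and neck motion: the cranium, the
cervical vertebrae, the thoracic spine treated as one element, sternum,
hyoid, thyroid, ribs, the pectoral girdle (scapulae, claviculae and, where
they carry neck muscles, humeri), the nuchal ligament where present, the
mandible where it carries relevant attachments, and every muscle of the
cervical motion system. Links are physical contacts: joints and ligamentous
articulations between skeletal elements, and the fleshy or tendinous
attachments of muscles onto bones. Bilateral elements appear as separate
left and right nodes (suffixes `l`/`r`). There are no weights and no
directions: the model deliberately records only *which* elements touch,
because it is the arrangement — not the size or strength — of the
connections that is being compared across species.

Networks enter the package as labelled 0/1 adjacency matrices
(`read_adjacency_matrix()`), CSV/TSV or one-sheet-per-species workbooks.
Validation is deliberately permissive where the biology is permissive:
species legitimately differ in which elements exist, so there is no global
node registry; unknown labels default to tissue `muscle` with a warning
(muscles dominate the vocabulary and are the labels most likely to vary);
asymmetric matrices are OR-symmetrized with a warning rather than rejected,
since hand-coded matrices often record each contact once. Disconnection is
a warning at read time but a hard error where it actually bites (mean path
length, module detection).

## The seven parameters

For a network with $N$ nodes and $K$ links the package computes:

* **Density** $D = 2K / (N(N-1))$ — the fraction of possible connections
  realised; read as morphological complexity.
* **Mean clustering coefficient** $C$ — the average over nodes of the
  fraction of a node's neighbour pairs that are themselves connected
  (3-node loops); read as integration by co-dependency. Nodes of degree
  $< 2$ contribute 0 by default; a flag drops them from the average instead
  for sensitivity analysis.
* **Mean shortest path length** $L$ — by default the mean geodesic distance
  over all unordered node pairs. Some sources print the non-normalised form
  $\frac{1}{N-1}\sum d_{ij}$; that convention is available by flag
  (`convention = "printed_sum"`), but printed comparative values of
  $L \approx 2.6$–$3.1$ at $N \approx 100$ are only consistent with the
  per-pair mean, which is therefore the default.
* **Heterogeneity** $H = \sigma_k / \mu_k$ — the coefficient of variation of
  the degree sequence (anisomerism). The population standard deviation
  ($1/N$) is the default, with the sample convention by flag; the printed
  values this package was checked against cannot discriminate the two
  without the original matrices, so both remain available.
* **Parcellation** $P = 1 - \sum_m (N_m/N)^2$ over a module partition: 0
  for a single module, approaching 1 for many uniform modules.

$N$, $K$, $D$, $C$, $L$, $H$ need only the graph; $P$ needs a partition
from the modularity analysis.

## Connectivity modules

A connectivity module is a set of nodes more densely connected internally
than externally. Partitions are scored with Newman–Girvan modularity

$$Q = \sum_m \left( \frac{e_{mm}}{K} - \left(\frac{d_m}{2K}\right)^2 \right)$$

and found by simulated annealing (`detect_modules()`), which at the
spin-glass default coupling is the same objective the classical
spin-glass/annealing toolchain optimises. The annealing state is the
node-to-module assignment; moves are single-node reassignments (to a
neighbouring or empty module, evaluated by an incremental $\Delta Q$), plus
module merges and random bisections; worsening moves are accepted with
probability $e^{\Delta Q / T}$. The schedule, unspecified in the sources
this design follows, is: initial temperature calibrated so roughly half the
sampled uphill moves are accepted; geometric cooling by 0.995 per sweep;
one node move per node plus $N/10$ merge/split proposals per sweep; stop
after 50 sweeps without improvement. A deterministic greedy polish then
exhausts single-node improvements, which is what lets small instances reach
the exact optimum (verified against exhaustive partition enumeration in the
tests). Every run takes an explicit seed; `consensus_modules()` reruns over
a seed vector, returns the best-$Q$ partition and the co-assignment
frequency matrix, which is where unstable left/right splits of bilateral
modules become visible.

Uncertainty in $Q$ uses a jackknife over links: each link in turn is
removed, $Q$ recomputed with the partition held fixed, and
$Q_{err} = \sqrt{\frac{K-1}{K}\sum_e (Q_{(-e)} - \bar Q)^2}$. A network is
called strongly modular when $Q - Q_{err} > 0.3$ (strict). Per-module
significance is a one-sided two-sample rank-sum test of the nodes'
internal-link counts against their external-link counts (alternative:
internal greater — the definition of a module). Where the full enumeration
of mid-rank combinations is feasible (${n_1+n_2 \choose n_1} \le 20000$)
the p-value is exact even under ties; larger modules use the standard
rank-sum implementation (exact up to 25 per sample without ties, otherwise
the tie-corrected normal approximation). No multiple-testing correction is
applied across modules; p-values are reported per module.

## Phylogenetic comparative layer

All comparative statistics operate on the species × parameter matrix plus a
calibrated tree, under Brownian-motion covariance
$C_{ij} =$ shared branch length.

* **Blomberg's K** — the observed ratio of non-phylogenetic to phylogenetic
  mean squared error, scaled by its BM expectation from the tree; $K = 1$
  under BM. Significance by tip-shuffling randomization.
  **K~mult~** is the same ratio on the stacked multivariate residuals and
  reduces exactly to $K$ for one trait. Traits are used on their measured
  scales by default with standardization by flag — whether published
  multivariate values were computed on standardized parameters is generally
  not stated, so both modes exist.
* **Abouheif's C~mean~** — Moran autocorrelation under the tree-topological
  proximity matrix $a_{ij} = \prod_k 1/dd_k$ over the interior nodes on the
  path between tips $i$ and $j$ (no branch lengths), permutation p-values.
* **Model comparison** — multivariate ML fits of BM, single-optimum OU and
  early burst sharing one tree transformation across traits with a full
  among-trait rate matrix (estimated analytically given the
  transformation). OU uses the ultrametric closed-form covariance; EB
  rescales each covariance entry by $(e^{rs}-1)/r$, $r \le 0$, collapsing
  onto BM at $r = 0$ (the boundary is checked explicitly so the nesting is
  never violated numerically). The single profiled parameter is optimised
  over a 10-point grid plus a bounded 1-D search — robust at the ~50-tip
  scale this package targets. AIC weights are reported across the three.
* **PGLS** — GLS through the Cholesky factor of $C$, F-test of the
  predictor against the intercept-only model in the GLS metric; identical
  to OLS on a star tree.
* **D-PGLS** — the multivariate distance-based variant: data and design are
  premultiplied by $C^{-1/2}$, F comes from sums of squares on the
  transformed fit, and significance from permutation of reduced-model
  residuals (RRPP). With one trait on a star tree it is classical one-way
  ANOVA.
* **Phylomorphospace** — PCA of the parameter matrix with internal nodes
  placed by BM ancestral estimates (the GLS/BLUP closed form) projected
  into PC space. The correlation matrix is the default: the parameters
  differ by two orders of magnitude ($K \sim 320$ vs $H \sim 1.4$), so
  covariance PCA would be dominated by $K$ alone; a published 44%/27%
  PC1/PC2 split on comparable data is only reproducible under the
  correlation convention, which this package's tests confirm on its shipped
  table. Covariance mode remains available by flag.

All permutation p-values use $(\#\{\ge obs\}+1)/(n_{perm}+1)$, so no test
can report $p = 0$.

## Variability of the parameters

Relative variability is compared through coefficients of variation (sample
SD over mean, the convention of the standard statistical toolchains).
Confidence intervals are percentile bootstrap over 10,000 resamples — the
minimal reading of "bootstrap resampling"; BCa is available by flag. The
global test for equality of CVs across the seven parameters is a modified
signed-likelihood-ratio test: the constrained (common-CV) likelihood is
profiled over the CV — for fixed CV the group means solve a quadratic, so
the profile is one-dimensional — and the LRT statistic is Bartlett-corrected
by parametric bootstrap under the fitted null, then referred to
$\chi^2_{k-1}$. On the shipped 48-species table this reproduces the
published statistic (≈ 139.6) to well under a percent. Pairwise comparisons
use the asymptotic (Feltz–Miller) $\chi^2$ test with Bonferroni correction
capped at 1, on raw parameters (logs are used elsewhere only where
regression calls for them).

## Disparity through time

Disparity of a tip set is its average squared pairwise Euclidean distance
in (by default) standardized PC scores, recomputed inside the module so the
analysis is invariant to trait scaling. Walking from the root to the
present through the internal nodes in time order, the curve value at each
divergence time is the mean relative disparity of the lineages alive just
before that divergence — a clade about to split still counts as one
subclade at its own divergence time, the convention of the established DTT
implementations; the curve starts at 1 and ends at 0. The null is $n_{sim}$
BM simulations on the same tree with the ML rate matrix estimated from the
data; the simulations are summarised by their median curve and pointwise
95% envelope. The MDI is the signed (trapezoid) area between the observed
curve and the simulated median over the full relative-time range (an
optional window restricts the integral to a sub-interval, off by default),
and $p$ is the fraction of simulations whose own MDI reaches the observed
one. MDI values for BM-generated data centre on zero, which is the
package's self-consistency check.

## The synthetic-data generator

The generator exists so that the whole pipeline — file round-trips, module
detection, comparative statistics — can be exercised against data whose
structure is known. `neck_template()` states the world: a serial bone chain
cranium–C1–…–C$n$–thoracic spine with girdle articulations, and a blueprint
of ~43 bilateral muscles (suboccipital, deep serial, prevertebral, scalene,
longissimus/iliocostalis, transversospinal, splenius, ventral strap and
neck–shoulder groups) with anatomically plausible origin/insertion sets of
2–10 elements. Defaults: seven cervical vertebrae; clavicle, mandible,
humerus and nuchal ligament present; attachment noise 0.15 — the
probability per muscle that one vertebral attachment is added or dropped,
chosen so that replicate networks vary in $K$ on the scale real congeners
vary in attachment sites while never stranding a muscle (two attachments
minimum). Under these defaults generated networks have ~110 nodes and
~290–330 links, inside the empirically observed ranges (84–130 nodes,
219–397 links), and their consensus modules reproduce the recurring
biological pattern: cranio-atlantal, mid-cervical (C2–C4), lower
cervical(–thoracic), ventral, with pectoral elements joining the
cranio-atlantal or ventral unit the way they do across real species.

What the generator does *not* emulate: real attachment-site correlations
between muscles, species-specific reductions (it will not reproduce any
actual species' wiring), or any link between a species' network and its
position on the simulated tree (trees are pure-birth, traits are simulated
separately). A green recovery test therefore establishes that the
*algorithms* behave as specified on neck-shaped inputs — not that any
biological conclusion is reproduced. Trees from `generate_tree()` are
Yule trees rescaled to a root age of 170 time units (the order of the
mammalian crown age in Ma); traits from `simulate_traits()` use the same
BM/OU/EB covariance transforms as the fitting code.

## Numerical choices and degenerate inputs

* Internal arithmetic is at full precision; rounding to 3 decimals happens
  only in reporting.
* Zero-variance traits, zero-mean groups, singular designs and
  single-level factors are hard errors with explicit messages; rank
  deficiency in a multivariate block and star-like (degenerate) proximity
  matrices are warnings.
* Ultrametricity is checked with a relative tolerance (default $10^{-6}$;
  $10^{-4}$ for the OU closed form).
* The annealing objective is tracked incrementally; the returned $Q$ is
  recomputable from the partition and the two always agree (tested).
* Seeds are explicit everywhere; internal RNG use saves and restores the
  caller's RNG state, and seed arguments are forced before that state is
  saved so expressions like `seed = sample.int(1e6, 1)` behave.

## Known limitations

* Module detection is stochastic; Table-style per-species module summaries
  should always come from `consensus_modules()` over many seeds, and module
  counts can differ by left/right splits of bilateral units (inspect the
  co-assignment matrix).
* The MSLRT's Bartlett correction is itself a Monte-Carlo estimate; its
  statistic carries simulation noise of a fraction of a percent at the
  default `nr`.
* OU fitting assumes an ultrametric tree; no measurement-error model, no
  multi-optimum OU, no weighted or directed networks, no overlapping or
  hierarchical modules.
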