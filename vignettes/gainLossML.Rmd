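---
title: "Gene gain/loss models and ancestral gene-content inference with gainLossML"
author: "gainLossML authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene gain/loss models and ancestral gene-content inference with gainLossML}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gainLossML)
```

## The inference problem

Given a rooted phylogeny of prokaryotic species with known branch
lengths, and the record of how many copies of each orthologous gene
family each genome carries, we ask: what is the probability that the
gene was present in the genome of the root ancestor — the last
universal common ancestor (LUCA)? The observed data for one gene is its
*phyletic vector*: one state per genome, either absent (`0`), present
in a single copy (`1`), or present as multiple in-paralogs (`m`).
gainLossML treats the evolution of this state along each branch as a
continuous-time Markov chain, fits the chain's rates per gene by
maximum likelihood, and reads the root state off the posterior.

## The model family

Four nested models are provided, differing in state space and in how
many rates are free:

* **B1** — binary states \{0, 1\}, one rate: gain and loss are equal
  (`c`). 1 free parameter.
* **B2** — binary, separate gain `g` (0→1) and loss `l` (1→0). 2
  parameters.
* **M1** — three states \{0, 1, m\} with gain `g1` (0→1), duplication
  `g2` (1→m), loss `l1` (1→0), paralog loss `l2` (m→1), and a tied
  direct-jump rate `c` for both 0→m and m→0. 5 parameters.
* **M2** — as M1 but with the two direct jumps free: `c1` (0→m, gain
  of several copies at once) and `c2` (m→0, loss of all copies at
  once). 6 parameters.

With state order (0, 1, m) the three-state rate matrix is

$$
Q = \begin{pmatrix}
-(g_1 + c_1) & g_1 & c_1\\
l_1 & -(l_1 + g_2) & g_2\\
c_2 & l_2 & -(l_2 + c_2)
\end{pmatrix},
$$

with diagonals chosen so each row sums to zero; M1 sets
$c_1 = c_2 = c$. The layout encodes the biological reading of the
parameters: the difference between M1 and M2 lies in whether losing
*all* copies of a duplicated gene in one sweep (m→0) is tied to the
rate of gaining several copies at once (0→m). The state order is fixed
and not configurable; every matrix in the package is labeled.

All rates are per unit branch length (the tree's substitutions-per-site
scale). Transition probabilities along a branch of length $t$ are
$P(t) = e^{Qt}$; the binary models also admit the closed form
$p_{00}(t) = (l + g e^{-(g+l)t})/(g+l)$, which the package exposes as
`twoStateClosedForm()` and uses as an independent check on the matrix
exponential.

```{r}
m2 <- RateModel("M2", g1 = .5, g2 = 1, l1 = 1.5, l2 = 2,
                c1 = .1, c2 = .3)
rateMatrix(m2)
round(transitionMatrix(m2, 0.35), 3)
```

## Likelihood and root posterior

For a gene's phyletic vector $X$ on the tree, the likelihood is

$$
f(X \mid \theta) = \sum_{y_0} \pi_{y_0} L_0(y_0),
$$

where $\pi$ is the prior over root states and $L_0(y_0)$ the
conditional likelihood of the leaves given root state $y_0$, computed
by Felsenstein's pruning recursion: a leaf's partial likelihood is the
indicator of its observed state, and an internal node's partial for
state $k$ is the product over children $c$ of
$\sum_j P(t_c)_{kj}\,L_c(j)$. The root posterior is then

$$
f(y_0 = k \mid X, \theta) = \frac{\pi_k L_0(k)}{f(X \mid \theta)},
$$

and the *presence probability* is $1 - f(y_0 = 0 \mid X, \theta)$.
`bruteForceLikelihood()` evaluates the same quantity by explicit
summation over all assignments of states to internal nodes; it is
retained as an independent oracle (it refuses trees with more than 8
internal nodes) and the test suite holds the two routes to within
$10^{-9}$ relative error.

### Root priors

The default three-state prior is $\pi = (0.5, 0.45, 0.05)$ over
(0, 1, m): even odds on presence, and a 9:1 split of the presence mass
between single-copy and duplicated states, reflecting the expectation
that the root genome carried relatively few in-paralog groups. The
binary default is flat (0.5, 0.5); the three-state prior's absence mass
is 0.5, and with nothing known about the binary split we mirror it
(this is overridable via `base`).

Optionally the prior is *frequency weighted*: the presence mass is
multiplied by the gene's occurrence frequency $w = n_\text{present} /
n_\text{total}$ across genomes and the vector renormalized. This
guards against occasional implausible absence calls for genes found in
nearly every genome. Two sharing rules are provided, because the
weighting statement alone does not fix how state m participates:
`mode = "both"` (default) scales states 1 and m jointly, preserving
their 9:1 internal ratio — the minimal reading — while
`mode = "single"` scales only state 1. When enabled,
`fitGeneContent()` applies the weighting uniformly to every gene; the
alternative of weighting only near-universal genes is a policy the
caller can implement by fitting strata separately.

## Fitting, model choice, and ancestral sets

Rates are estimated by maximizing the log-likelihood, per gene or
pooled (shared rates, summed log-likelihoods across genes). Models
within a state-space family are compared by AIC $= -2\ell + 2p$
($p$ = 1, 2, 5, 6 for B1, B2, M1, M2); the lower AIC wins and exact
ties go to the smaller model. Comparisons across families (say M1 vs
B2) are refused: the two likelihoods are computed on different
encodings of the data and their AICs are not commensurable.

Per-gene fitting mirrors how the method is used on real cohorts — every
gene gets its own rates and its own AIC choice — but a single vector
contains little information about five or six rates, so per-gene
estimates are noisy and often sit on the optimizer bounds. The pooled
mode is the appropriate tool for parameter-recovery experiments and for
cohort-level rate statements; both are first-class.

The ancestral gene set at threshold $x$ (`buildAncestralSet()`)
collects the genes whose presence probability under their AIC-preferred
three-state model is at least $x$; `ancestralCountSeries()` tabulates
the (non-increasing) count across $x \in \{0.5, 0.55, \ldots, 1\}$.
`medianTransitionSummary()` reports the entrywise median of $P(t)$
across fitted genes — a population summary of per-branch dynamics,
conventionally evaluated at the tree's median branch length (reported
by `validateTree()`); rows of a median matrix need not sum to 1.

The aggregate loss-to-gain rate ratio is reported as
$(l_1 + l_2 + c_2) / (g_1 + g_2 + c_1)$ for M2 (M1 with $c_1 = c_2 =
c$; $l/g$ for B2; 1 for B1 by construction). Pooling all
loss-direction rates over all gain-direction rates is a package choice
— there are several defensible aggregations of five or six rates into
one number — so the per-pair ratios $l_1/g_1$, $l_2/g_2$, $c_2/c_1$
are always reported alongside and nothing is hidden in the aggregate.

## Horizontal transfer as vector editing

The models assume vertical descent. When an external analysis
identifies a horizontal transfer of a gene into a clade, the presences
in the recipient clade carry no signal about the root, and
`hgtEditVector()` (or the `cmdHgtEdit()` command) resets those
coordinates to absence before refitting. Detection of transfers is out
of scope; only the editing consequence is implemented.

## The simulator

`simulateGenes()` draws each gene's root state from the prior and then
states down the tree from the rows of $P(t)$ per branch — exactly the
generative process the likelihood integrates over. Node states rather
than event times are simulated; since the likelihood only ever sees
node states, this is exact for every quantity the package computes
(event-level simulation of the chain is a non-goal). Counts are
written with 2 representing state m. True root and internal states are
retained, so recovery and calibration studies need no external data.

What the generator deliberately does *not* emulate: horizontal
transfer, lineage- or branch-specific rate shifts, correlated evolution
between genes, and genome-sampling artifacts of real ortholog
databases. Tests that pass on simulated data therefore validate the
estimator under its own assumptions — they do not certify robustness to
the model violations real phyletic data contain.

## Numerical choices

* **Matrix exponential.** `transitionMatrix()` uses the
  scaling-and-squaring exponential from the Matrix package. Inside the
  fitting loop, all branch lengths are served from one spectral
  decomposition of $Q$ ($P(t) = V e^{\Lambda t} V^{-1}$ evaluated as a
  single matrix product over unique lengths); every decomposition is
  probed against the scaling-and-squaring result at the longest branch
  and the code falls back to per-length exponentials if the probe
  deviates beyond $10^{-10}$. Entries are clamped to $[0,1]$ and rows
  renormalized against roundoff.
* **Underflow.** Pruning rescales each node's partials by their
  per-gene maximum and accumulates the log of the scale, so
  likelihoods on trees with a hundred-plus leaves are computed without
  underflow; a 103-leaf star-tree identity in the test suite pins the
  scaled recursion to an independent log-space formula at $10^{-9}$.
* **Optimization.** On log-rates, bounded to rates in
  $[10^{-6}, 100]$, with L-BFGS-B; convergence when the log-likelihood
  improves by less than $10^{-8}$. Multi-start: one central start (all
  rates 1), seeded jittered starts, and — for B2 and M2 — a warm start
  at the nested smaller model's optimum, which enforces
  $\ell(\mathrm{M2}) \ge \ell(\mathrm{M1})$ and
  $\ell(\mathrm{B2}) \ge \ell(\mathrm{B1})$ up to tolerance. Among
  equal optima the smaller log-rate L2 norm wins. Estimates on a bound
  are flagged (`bound_hit`) as a non-identifiability signal rather
  than silently clipped.
* **Degenerate inputs.** All-absent vectors are refused as
  non-identifiable (with rates free, absence everywhere is explained
  arbitrarily well by "never existed"); zero-length branches contribute
  $P(0) = I$; a likelihood of exactly zero (possible only with
  boundary rates) makes the posterior undefined and errors rather than
  returning NaNs. Universal genes are retained and fitted like any
  other — their high presence probability emerges from the likelihood,
  not from a rule.

## Validation scale

The checks shipped with the package run at sizes chosen to exercise
every code path at full tolerance while staying desk-sized: the
pruning-vs-enumeration sweep uses 200 random instances on trees of 2-6
leaves; parameter recovery simulates 1000 genes under M2
($g_1 = 0.5$, $g_2 = 1$, $l_1 = 1.5$, $l_2 = 2$, $c_1 = 0.1$,
$c_2 = 0.3$) on a 32-leaf tree with uniform branch lengths in
$[0.01, 1]$ (bracketing the 0.35 median-branch scale typical of deep
prokaryote trees) and requires every pooled-fit rate within 25%;
nested-likelihood dominance is asserted per gene on a 40-gene subset
of that cohort plus the pooled fits; simulator calibration compares
single-branch transition frequencies against $P(t)$ rows at 10,000
replicates within three binomial standard errors. These sizes are the
package's validation design, balancing coverage against the few
minutes a test suite should take.

## A small worked run

```{r}
set.seed(20)
tree <- ape::rtree(16, rooted = TRUE)
tree$edge.length <- runif(nrow(tree$edge), 0.1, 0.7)
tree$tip.label <- paste0("sp", 1:16)
sim <- simulateGenes(tree, m2, nGenes = 10, seed = 7)
prof <- PhyleticProfiles(sim$counts, tree)
prof
res <- fitGeneContent(prof, families = "three-state",
                      weighting = TRUE, restarts = 2, seed = 1)
res$table[, c("gene_id", "model", "presence_probability",
              "loss_gain_ratio")]
presence <- setNames(res$table$presence_probability,
                     res$table$gene_id)
ancestralCountSeries(presence)
```

With the generating rates known, the posterior can also be checked for
calibration directly (genes whose presence probability is, say, 0.7
should be truly root-present about 70% of the time over many simulated
genes); the package's validation suite does this at larger simulation
sizes.

## Limitations

Rates are constant across branches (no lineage effects), genes are
independent, the tree is fixed and error-free, and missing data are not
modeled — a genome not assayed must be coded explicitly, since silent
imputation would change likelihoods invisibly. Per-gene estimates of
five or six rates from one vector are intrinsically noisy; treat
per-gene rate ratios as descriptive and prefer pooled fits for rate
inference. The root prior matters most for sparsely distributed genes,
exactly the regime where the likelihood is flattest; sensitivity to the
prior is worth checking in any application.
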