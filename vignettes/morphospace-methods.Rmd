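---
title: "A mesoscopic morphospace for functional brain networks: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mesoscopic morphospace for functional brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnmorph)
```

## The model

A functional connectome is a weighted, undirected graph over brain regions:
a symmetric matrix $A = [w_{ij}]$ of functional couplings in $[0,1]$, one
matrix per subject, condition (rest or task) and session (test, retest).
Given an a-priori partition into functional networks (communities), `fnmorph`
asks, for each community $\mathcal{C}$: how strongly does this community hold
on to diffusing signal, and how selectively does it hand signal over to the
rest of the brain?

Both questions are answered by one construction, a *terminating (absorbing)
Markov chain*. The community's own nodes are the transient states
$S_{trans} = V_\mathcal{C}$; every outside node with a positive coupling to
the community is an absorbing state ($S_{abs}$). On the induced submatrix
$A_\mathcal{C}$ (rows/columns ordered transient-first), the transition matrix
is the strength-normalized

$$Q = D_\mathcal{C}^{-1} A_\mathcal{C}, \qquad
P = \begin{pmatrix} Q_{tt} & Q_{ta} \\ 0 & I \end{pmatrix},$$

where $D_\mathcal{C}$ holds each state's strength (row sum over all of
$S$) — summing over the full state set is the only normalization under which
$Q$'s transient rows are stochastic and $P$ is a Markov chain. Standard
absorbing-chain algebra then gives the fundamental matrix
$Z = (I - Q_{tt})^{-1}$ (expected visit counts), the mean time to absorption
$\tau = Z\,\mathbf{1} \ge 1$, and the absorption probability matrix
$\Psi = Z\,Q_{ta}$ with row sums 1.

Two mesoscopic coordinates summarize the chain:

* **Trapping efficiency** $TE = \lVert\tau\rVert_2 / \mathcal{L}_\mathcal{C}$
  (steps/weight), with $\mathcal{L}_\mathcal{C}$ the total exiting strength
  (the L1 mass of the transient-to-absorbing block). The L2 numerator
  accentuates configuration differences; the L1 denominator accounts for
  community size through its leakage. High TE = a segregated module.
* **Exit entropy** $EE = -\sum_j \psi_j \log \psi_j \,/\, \log|S_{abs}|$,
  where $\psi$ averages the rows of $\Psi$ over start nodes. EE depends only
  on the *distribution* of exit couplings, not their magnitude (rescaling all
  exits by $c$ doubles neither $\psi$ nor EE but scales TE by $1/c$ — a
  property the test suite checks explicitly). Low EE = preferential,
  specific integration.

Each (subject, condition, session, community) becomes a point $u(\mathcal{C})
= (TE, EE)$ in the 2D morphospace $\Omega$.

**Configural breadth.** Per subject and community, the task points $W$ span a
polytope: *functional reconfiguration* $\mathcal{R}$ is the area of
$\mathrm{Conv}(W)$, and *functional preconfiguration* $\mathcal{P}$ is the
Euclidean distance from the resting-state point to the arithmetic centroid
$\eta(W)$. The pair $(\mathcal{R}, \mathcal{P})$ is a community's configural
breadth record.

**Cohort statistics.** Sensitivity analyses use the one-way random-effects
intraclass correlation $\mathrm{ICC} = (MSB - MSW)/(MSB + (n-1)MSW)$ in three
designs (tasks within subject, tasks across the cohort, subjects), each
contrasted with a permutation null. Behavior is modelled by an iterative
multilinear model: descriptors enter in descending order of subject
sensitivity, nested OLS fits on z-scored variables are compared by overall
$F$-test p-value, and the selected model's specificity is estimated by
repeated 5-fold cross-validation against a noise null.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `symmetry_tol` | 1e-8 | weight | asymmetry below this is numerical noise and is averaged away; larger asymmetry means the input is not an undirected connectome and is an error |
| `start` (exit aggregation) | `"uniform"` | — | the start distribution over transient nodes is not dictated by the chain; uniform is the minimal assumption, `"strength"` is the alternative |
| `norm` (TE numerator) | 2 | — | L2 accentuates configuration differences; exposed but non-default alternatives exist for sensitivity checks |
| ICC variant | one-way ICC(1,1) | — | the minimal-assumption form for class/replicate designs; two-way variants would assert session fixed effects the protocol does not define |
| `n_perm` | 999 | — | permutation nulls with the add-one p estimator; p-values are then valid (conservative) by construction |
| `k`, `n_sim` (specificity) | 5, 2000 | — | repeated k-fold CV; the mean of the five fold correlations is the per-simulation statistic |

## Numerical choices and degenerate inputs

* Negative couplings are zeroed (they are not modelled), the diagonal is
  forced to zero (self-loops would inflate $\tau$ arbitrarily), and weights
  above 1 are allowed with a warning — the finite TE bound is only
  characterized for weights in $[0,1]$.
* $Z$, $\tau$, $\Psi$ come from linear solves of $(I - Q_{tt})X = B$, not an
  explicit inverse chained through products.
* A community equal to the whole graph, or with no exit edges, has no
  absorbing states: a degenerate-community error. A transient node with zero
  strength is an error naming the node (silent dropping would change the
  state space). A transient subchain that cannot reach any absorbing state
  makes $I - Q_{tt}$ singular: an absorption-unreachable error.
* A single exit node makes the EE normalizer $\log 1 = 0$; the exit
  distribution on one support point is uniform, so EE is defined as 1, with
  a warning. $0\log 0 := 0$ throughout.
* Hulls are computed at their true affine dimension. The headline
  $\mathcal{R}$ is strictly the 2D area — collinear task points give 0 —
  with the affine dimension and the lower-dimensional measure (segment
  length) reported alongside, so degenerate configurations are visible
  rather than silently inflated. Hull vertices are ordered counterclockwise
  from the lexicographic minimum and collinear edge-interior vertices are
  pruned, making vertex sets deterministic.
* The centroid $\eta(W)$ is the arithmetic mean of the task points, the only
  centroid defined at every affine dimension; tasks are unweighted.
* Ties in descriptor ranking and maximal-distance pairs break
  alphabetically, so orderings are reproducible.
* Breadth is computed per session by default; averaging sessions before
  hull construction is exposed as an option (`average_sessions`).

## What the synthetic cohort emulates

`cohort_spec()` generates test-retest cohorts shaped like a large human
imaging release: by default 100 subjects, rest plus seven tasks, two
sessions, 374 regions in eight communities (seven cortical resting-state
networks and a subcortical group, sizes 61/57/46/47/26/52/71/14). Couplings
are truncated-normal draws clamped to $[0,1]$ around block means
($\mu_{in} = 0.30$ within, $\mu_{out} = 0.08$ between, per-edge sd
$\sigma_w = 0.04$) — values in the range of group-level functional
connectivity after negative-coupling removal.

Three planted effect layers target the exact mechanisms the metrics measure:

* **Subject effects** ($\sigma_{subj} = 0.06$): per subject and community,
  an additive offset on within-community couplings in every condition — a
  stable segregation level, the fingerprint that trapping efficiency reads —
  plus a rest-only within-community offset of the same sd. The second
  component exists because any effect constant across conditions shifts the
  rest point and the task centroid together and cancels exactly in
  preconfiguration; a subject's rest-vs-task contrast must itself be a
  trait for $\mathcal{P}$ to carry a fingerprint, which is precisely the
  claim preconfiguration quantifies. The magnitude matches the well
  documented scale of individual differences in within-network coupling.
* **Task effects**: per (task, community) multipliers on exit edges. The
  default map has task $t$ concentrate every community's exits into a
  rotating target community with multiplier $1 + 0.1t$: concentration moves
  exit entropy down, magnitude moves trapping efficiency, and the
  task-varying strength separates task means.
* **Scan noise** ($\sigma_{sess} = 0.02$): each (subject, condition,
  session) matrix is one scan run and receives an independent gain
  fluctuation — all means scaled by $1 + N(0, \sigma_{sess})$. A gain leaves
  $\tau$ invariant (normalization cancels it) and scales TE by the inverse
  gain, emulating global coupling-level shifts between scans without
  creating edges where none exist. An additive run offset was rejected: at
  $\mu_{out} = 0.08$ it would swing total exiting strength by tens of
  percent per scan and turn structural zeros into edges.

Every generated matrix already satisfies the sanitization invariants, and
each matrix is reproducible in isolation from hashed substreams of one base
seed.

What the generator does **not** emulate: empirical FC spectra,
distance-dependent coupling, hemispheric structure, BOLD autocorrelation,
heavy-tailed motion artifacts, or community-specific coupling levels.
Passing recovery tests therefore show that the estimators read out the
mechanisms they claim to measure — not that effect sizes on real data will
match.

## Design choices where the design was open

* **Strength normalization over the full state set.** Summing node strength
  only over community nodes would leave $Q$'s rows summing below 1 and $P$
  would not be a transition matrix; the block structure of $P$ forces the
  full-set convention.
* **Uniform start for $\psi$.** The exit distribution must aggregate
  $\Psi$'s rows; nothing in the construction picks a start law, so the
  uniform one is the default and a strength-weighted start is an option.
* **Rest is excluded from the task hull.** Preconfiguration is drawn from
  rest *to* the task hull; including rest in $W$ would make the two
  components partially redundant.
* **Gaussian specificity null.** The noise response in the specificity null
  is a fresh standard-normal vector per simulation; a permutation variant
  (`null_type = "permutation"`) is provided, and the two coincide in
  distribution for exchangeable responses.
* **Breadth descriptors feed behavior models session-averaged**, matching
  one score per subject.

## Problem sizes used by the test suite

The validation suite runs the full pipeline at deliberately chosen sizes:
hand-solved toys for exact algebra; twenty random graphs of up to 40 nodes
against a $2\times10^4$-walker Monte-Carlo oracle per start node (with
hundreds of simultaneous z-comparisons, agreement is asserted as at least
99% of deviations within 3 SE and none beyond 5 SE); one hundred random
point sets against an $O(n^4)$ hull oracle; two hundred label-shuffled
datasets with 999 permutations each for null calibration; planted-effect
recovery on 20-subject cohorts at the full 374-node default shape; and
behavior-model recovery on a 100-subject cohort with 12-node communities.

## Known limitations

* Power to detect subject fingerprints in preconfiguration grows with
  community size: the planted rest-contrast signal is coherent over a
  community's within edges while scan-gain noise is a constant fraction of
  TE for every community, and taking the magnitude of the rest-centroid
  difference folds away its sign. In the default cohort the smallest
  community (14 subcortical regions) sits at its permutation-null detection
  bound at 20 subjects; larger cohorts or larger communities separate
  cleanly.
* Preconfiguration mixes the raw TE and EE axes, whose numerical scales
  differ by orders of magnitude; distances are therefore dominated by the
  TE axis. This follows the definition of the measure in raw morphospace
  units; users comparing communities of very different sizes should keep
  axis scales in mind.
* Directed or signed connectomes, continuous-time chains, and 3D+
  morphospaces are out of scope. Negative couplings carry information the
  framework discards by construction.
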