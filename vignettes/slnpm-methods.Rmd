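---
title: "Methods: linear neighborhood propagation for bipartite interaction prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linear neighborhood propagation for bipartite interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slnpm)
```

## The model

The package predicts links in a bipartite lncRNA–miRNA network from two
information sources available for every transcript: its sequence and its
(possibly empty) interaction profile. Three assumptions drive the design:

1. **Local linearity.** An entity's representation can be reconstructed as
   a convex combination of its nearest neighbors' representations; the
   reconstruction weights are a meaningful, directed similarity.
2. **Guilt by association.** Entities similar to a miRNA's known lncRNA
   partners are themselves likely partners; formally, interaction labels
   diffuse along the similarity graphs.
3. **Sequence–interaction coupling.** Transcripts with similar k-mer
   composition tend to have similar interaction partners. This is the
   weakest of the three and is used only where interaction information is
   absent (cold start).

### Linear neighborhood similarity

Given feature vectors $x_1,\dots,x_n$ (rows of $X$), the $K(n-1)$ nearest
neighbors of each point by Euclidean distance are marked in an indicator
matrix $C$ (self excluded, distance ties broken by ascending index), and
the weight matrix $W$ minimizes

$$\tfrac12\lVert X-(C\odot W)X\rVert_F^2+\tfrac{\mu}{2}\sum_i\big((C\odot W)e\big)_i^2
\quad\text{s.t.}\quad (C\odot W)e=e,\; W\ge 0 .$$

The problem separates into one convex quadratic program per row over the
probability simplex of its neighborhood. The package solves these rows
**exactly**, jointly, by accelerated projected gradient descent (FISTA)
with a descent safeguard: a candidate momentum step that would increase
the objective is replaced by a plain projected gradient step, so the
objective is non-increasing at every accepted iterate. The step size is
$1/\lambda_{\max}(XX^\top)$, computed once. Euclidean projection onto the
simplex uses the standard sort-based algorithm.

A popular alternative is a multiplicative fixed-point update derived from
the KKT conditions under the approximation that each row's multiplier
equals $\mu$ (valid when reconstruction error is negligible). We measured
that this shortcut can land up to 0.45 per entry away from the true
constrained optimum on generic inputs, so it is not used: the optimization
problem, not a particular heuristic for it, defines the similarity. The
test suite verifies row-by-row agreement with an independent
general-purpose QP solver.

Two consequences of solving the constraint exactly are worth noting:

* the $\mu$ term is constant on the feasible set, so the learned $W$ does
  not depend on $\mu$. The parameter is retained in `lns_config()` and in
  `lns_objective()` because the objective is defined with it and because
  penalty-type solvers (which enforce the constraint only approximately
  through $\mu$) are a natural extension point;
* $W$ is invariant to positive rescaling of $X$ for **every** $\mu$, not
  only $\mu=0$.

Uniform initialization over the neighborhood ($1/k$ on the support) is
feasible and unbiased; since the row problems are convex the solution does
not depend on it, only the iteration count does.

### Cold-start combination

Entities without known interactions have all-zero profiles; their
interaction-profile similarity rows and columns are kept at zero rather
than fabricated. Two strategies make such entities predictable:

* **SC** substitutes, row-wise and without blending, the sequence
  similarity row wherever the profile row is unavailable. The result is
  asymmetric; propagation treats it as a directed graph.
* **PC** rebuilds the missing profile as the similarity-weighted average
  of the profiles of the `k_nn` most sequence-similar entities that have
  at least one interaction, normalizing by the summed similarity, then
  learns both interaction similarities from the completed matrix.
  Complemented entries are convex combinations of binary profiles, hence
  in $[0,1]$, and the operation is idempotent. When all selected
  similarities are zero the unweighted neighbor mean is used (with a
  warning) rather than failing.

In the PC pipeline the completed matrix is also what is propagated as
initial labels — the complementation is treated as overwriting the
interaction matrix, not as a side computation — so a cold entity
contributes its reconstructed profile both through the graph and through
the label injection term.

### Label propagation and fusion

On a row-stochastic similarity graph $S$ the scores iterate
$F \leftarrow \alpha S F + (1-\alpha) Y$ from $F = Y$. With absorbing
probability $\alpha < 1$ the spectral radius of $\alpha S$ is below one
and the iteration converges to $(1-\alpha)(I-\alpha S)^{-1}Y$; the closed
form is implemented as a second, independent code path and the two are
cross-checked in the tests. Known pairs are not clamped beyond the
persistent $(1-\alpha)Y$ injection. Rows of $S$ summing to zero (isolated
nodes, e.g. cold entities in a profile-only model) are allowed: such a
node retains $(1-\alpha)$ of its own label and receives nothing. Label
mass is conserved column-wise only when $S$ is doubly stochastic, not for
general row-stochastic operators; the property test uses a Birkhoff
construction accordingly.

The lncRNA-graph propagation (one column of $Y$ per miRNA) yields $P^l$,
the miRNA-graph propagation yields $P^m$, and the final score is
$\beta P^l + (1-\beta)P^m$.

## Parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `k` | k-mer length | 5 | 1024 features; rows are frequencies over counted windows |
| `neighbor_ratio` (K) | fraction of the other $n-1$ points used as neighbors | 0.8 (SC), 0.9 (PC) | `max(1, floor(K(n-1)))` neighbors |
| `mu` | tradeoff weight of the row-sum term | 1 | inert under the exact constraint (see above) |
| `alpha` | absorbing probability of the diffusion | 0.4 | in $[0,1)$; larger spreads labels further |
| `beta` | fusion weight of the lncRNA-graph scores | 0.25 | 0.75 of the weight is on the miRNA graph |
| `k_nn` | PC complementation neighbors | 10 | small against both entity counts, averages single-neighbor noise |
| `max_iter`, `tol` (LNS) | solver budget | 100, 1e-6 | relative Frobenius change; tests use tighter settings for oracle comparisons |
| `max_iter`, `tol` (propagation) | solver budget | 1000, 1e-8 | geometric convergence at rate $\alpha$ |

`grid_search()` evaluates K ∈ {0.1,…,0.9}, α ∈ {0.1,…,0.9},
β ∈ {0,0.05,…,1} by default, reusing the β-independent propagation
components per (K, α) fold.

## Numerical and protocol choices

* **Alphabet.** `U` ≡ `T`; windows containing `N` contribute no k-mer
  count; any other letter is a hard error naming the record. Frequencies
  (not raw counts) are used because transcript lengths differ by orders of
  magnitude.
* **Determinism.** All ranking ties (neighbor selection, top-k cutoffs,
  prediction output) break by ascending index or lexicographic id, and all
  randomized operations take explicit seeds and restore the caller's RNG
  state, so every pipeline run is bit-reproducible.
* **Cross-validation.** Known positives are split into 5 near-equal folds;
  per fold, the fold's positives are masked to 0 and the *entire* pipeline
  — profile similarities and cold-start combination included — is rebuilt
  on the training matrix, so held-out information can never leak through a
  similarity. Metrics are computed per fold over all pairs except training
  positives (the full unobserved complement serves as negatives; no
  sampling) and averaged; run $r$ of $n$ uses seed $s+r-1$.
* **Metrics.** AUC is the rank (Mann–Whitney) statistic with ties counting
  one half; AUPR is non-interpolated average precision (interpolation
  overestimates). The thresholded metrics use a rank cutoff at the number
  of positives in the evaluated set — parameter-free and invariant to
  monotone score transforms — with a numeric-threshold override.
* **Degenerate inputs.** Duplicate ids, empty sequences, sequences shorter
  than $k$, unknown ids in the interaction list (strict by default, with a
  skip-with-warning mode), single-class metric calls, non-stochastic
  propagation operators and residual all-zero profiles after PC all fail
  fast with informative errors.

## The synthetic generator

`simulate_network()` emulates the joint structure the method exploits:
entities belong to one of `n_groups` groups; sequences are sampled from a
group-specific first-order nucleotide chain in which each base prefers one
group-specific successor by a factor `kmer_bias` (a first-order chain
rather than i.i.d. letters, because i.i.d. letters would give every
transcript the same expected k-mer profile); interactions are Bernoulli
with `p_in` within matching groups and `p_out` across. Defaults —
120 lncRNAs × 60 miRNAs, 4 groups, `p_in` = 0.5, `p_out` = 0.02,
`kmer_bias` = 20, 500-nt lncRNAs and 22-nt (mature-length) miRNAs — are
the study conditions used throughout the tests and the acceptance script.
The 22-nt miRNA length matters: mature miRNAs yield only 18 5-mer windows,
so their sequence features are far noisier than their interaction
profiles, reproducing the realistic regime in which known interactions
carry more information than sequence composition. The test protocol runs
3 repetitions of 5-fold cross-validation at this size, which keeps the
whole suite within a few minutes on a single core while leaving the
stochastic margins comfortable.

What the generator does **not** emulate: real nucleotide composition and
length distributions, hub-dominated degree distributions, overlapping or
hierarchical interaction modules, and database ascertainment bias. Passing
tests on planted structure therefore demonstrate correctness of the
machinery and the qualitative behavior of the combination strategies, not
expected performance on any real interactome.

## Known limitations

* Similarities are dense $n\times n$ matrices and propagation solves are
  dense; the implementation targets the few-hundred-entity scale typical
  of curated interaction sets, not genome-wide catalogs.
* The SC similarity switch is hard: an entity with a single (possibly
  spurious) interaction is treated as fully profiled.
* With very sparse training folds, profile-LNS reconstruction targets the
  masked zeros, which mildly depresses scores of held-out positives; this
  is inherent to learning similarities from the same matrix that is being
  completed.
* Sequence features are overlapping k-mer frequencies only; no secondary
  structure, no binding-site models.
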