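---
title: "Bidirectional label propagation for bipartite association prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional label propagation for bipartite association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bipartiteLP)
```

## The problem

Curated disease–microbe association catalogues are small, sparse, binary
tables: a one means some study implicated that microbe in that disease, a
zero means *no record* — not evidence of absence. The prediction task is to
rank the zero cells so the most plausible unrecorded associations surface
first. `bipartiteLP` implements a similarity-propagation approach to this
problem: similarity between entities is derived entirely from the
association table itself, and evidence is diffused over the two resulting
similarity networks.

The same machinery applies unchanged to any binary bipartite link
prediction problem (drug–target, gene–phenotype, host–parasite), which is
why every function works on a generic `AssociationMatrix`.

## The model, step by step

### Gaussian interaction profile kernels

The interaction profile of disease $d_i$ is row $i$ of the adjacency matrix
$A$; the profile of microbe $m_j$ is column $j$. Similarity between two
diseases is the Gaussian kernel of their profile distance,

$$SD(d_i,d_j) = \exp\!\left(-\gamma_d \lVert IP(d_i) - IP(d_j)\rVert^2\right),
\qquad
\gamma_d = \gamma'_d \Big/ \tfrac{1}{N_D}\sum_k \lVert IP(d_k)\rVert^2,$$

and symmetrically for microbes. Normalising the bandwidth by the mean
squared profile norm (the mean association count) makes the kernel
scale-free with respect to catalogue density; the raw bandwidth $\gamma'$
stays at its conventional value 1 on both axes. Because the kernel of any
two binary profiles is strictly positive, both similarity networks are
fully connected.

Two properties matter downstream and are asserted in the tests: the kernel
is exactly symmetric with unit diagonal, and at fixed bandwidth similarity
decreases monotonically in profile (Hamming) distance.

**Degenerate input.** If *every* profile is all-zero the bandwidth
normaliser is zero and the kernel is undefined; `gipKernel()` raises an
error. Cross-validation can produce this situation on tiny matrices (a
fold removes the only association an axis has), so the CV engines enable a
fallback, $\gamma = \gamma'$, under which all-zero profiles are handled
gracefully (their distance to any profile is that profile's squared norm).

### Neighbour-restricted normalisation

Label propagation should draw on a node's most similar peers, weighted by
similarity. For each row, a neighbour set $Q_i$ is chosen and the retained
similarities renormalised to sum to one:

$$S^*(i,j) = \begin{cases} S(i,j) \big/ \sum_{k \in Q_i} S(i,k) & j \in Q_i \\
0 & \text{otherwise.} \end{cases}$$

The parameter $K$ (default 5) admits two readings, and the package ships
both:

* **`literal`** (default): $Q_i$ is every node except $i$ itself and the
  $K$ nodes *least* similar to $i$, so $\lvert Q_i\rvert = n-1-K$. This
  trims only the weakest tail and leaves a dense weight matrix.
* **`topk`**: $Q_i$ is the $K$ *most* similar nodes — the standard KNN
  graph used in most label-propagation literature.

The literal rule is the default because it matches the way the
neighbour-set is usually stated for this method family; the `topk` flag
exists because the two readings are easy to confuse in prose and give
different networks. Ties at either boundary are broken by ascending column
index, so the construction is deterministic. Note $K = 0$ under `literal`
is plain row normalisation, while under `topk` it produces empty neighbour
sets (all-zero rows) — accepted, and propagation then simply retains
initial labels.

### Bidirectional propagation

On the disease network each node's label is its association row; one round
of updating absorbs the propagated *initial* labels with probability
$\alpha$ and retains the previous label with probability $1-\alpha$:

$$LD^k = \alpha \, SD^* A + (1-\alpha)\, LD^{k-1}, \qquad LD^0 = A.$$

The propagated term is constant across rounds — the recursion is affine
with a fixed source, not the classical
$\alpha S^* L^{k-1} + (1-\alpha) L^0$ form. This is a deliberate design
choice, kept because it is how the update is defined for this method; the
classical recursion is available behind `classicLP = TRUE` for comparison.
The constant-source form has a closed solution,

$$LD^k = \left(1-(1-\alpha)^k\right) SD^* A + (1-\alpha)^k A,$$

so the change between consecutive iterates decays *exactly* geometrically
with ratio $1-\alpha$, convergence (entry-wise L1 change below
$P = 10^{-12}$) is guaranteed for any $\alpha \in (0,1]$, and the number
of rounds is predictable from the first change alone. The test suite
asserts both facts on randomised instances; the default iteration cap of
1000 is a safety net only (about 130 rounds are needed at the defaults).

The score matrix sums every iterate, $W_{LPD} = LD^0 + \dots + LD^{n_1}$
(the sum includes the initial labels; the converged iterate count $n_1$ is
reported in the `PropagationTrace`). The microbe network runs the same
recursion with $A^\mathsf{T}$, and its score sum is transposed back to the
diseases × microbes orientation — the fusion below is dimensionally
impossible otherwise. Summing rather than taking the fixed point preserves
a strong contribution from the original labels; since the sum is a
positive combination of $S^*L^0$ and $L^0$ only, rankings are insensitive
to the exact number of accumulated terms once near convergence.

### Fusion

$$W = \beta\, W_{LPM} + (1-\beta)\, W_{LPD}, \qquad \beta = 0.75.$$

As written, $\beta$ weights the *microbe-side* matrix. Descriptions of
this method family disagree internally about which side the 0.75 belongs
to; the package implements the formula as printed above and documents
that swapping $\beta \leftrightarrow 1-\beta$ flips the convention. On
HMDAD-shaped data the microbe axis is an order of magnitude larger than
the disease axis, which is the usual argument for asymmetric weighting.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.2 | absorption probability; small values retain more of the previous label, and convergence speed is $-1/\log(1-\alpha)$ rounds per decade |
| `beta` | 0.75 | fusion weight on the microbe-side score matrix |
| `kNeighbors` | 5 | neighbour-set parameter $K$ (see the two modes above) |
| `neighborMode` | `literal` | which tail of the similarity ranking $K$ removes/keeps |
| `thresholdP` | $10^{-12}$ | L1 convergence threshold; scores are sums, so looser thresholds change absolute values but barely change rankings |
| `maxIter` | 1000 | safety cap; a truncated trace carries a flag and a warning |
| `gammaPrimeD`, `gammaPrimeM` | 1 | raw kernel bandwidths |
| `gammaFallback` | off (on inside CV) | $\gamma = \gamma'$ when a profile set is entirely zero |

## Cross-validation design

* **Negative pool.** A held-out pair is ranked against all pairs that are
  zero in the *original* matrix; held-out positives are never counted as
  negatives.
* **Leak-free by default.** Inside every fold the kernels, neighbour sets
  and normalisations are recomputed from the reduced matrix. Reusing
  full-matrix kernels lets the held-out edge leak into the similarity
  network; the effect is not subtle — on structure-free null data the
  leaky variant scores far above chance purely from the leak, which is
  why `refitSimilarity = FALSE` exists only as an explicitly requested
  variant (`--no-refit-similarity`) for comparability with
  implementations whose fold handling is unknown.
* **Fold AUC and pooling.** The LOOCV headline number is the mean over
  folds of the held-out pair's win fraction against the negative pool
  (ties one half); `pooling = "pooled"` builds one global ranking instead.
  k-fold AUC is the per-fold rank AUC averaged over folds, then averaged
  over repeats, reported with the sample standard deviation across
  repeats.
* **RNG.** One integer seed; repeat $r$ uses the stream `seed + r - 1`.
  Two runs with the same seed are identical to the bit.
* **A known bias.** Zeroing a test edge lowers its endpoints' degrees in
  the training matrix, and propagation mass correlates with degree, so
  held-out pairs score systematically slightly low relative to the
  full-degree negative pool. On structure-free data this shows up as a
  mean AUC a little *below* 0.5 (typically a few hundredths) with a
  spread across matrices that dwarfs the repeat-to-repeat standard error.
  This is a property of leave-out evaluation of degree-sensitive scores,
  not an implementation artefact — the package's pipeline has been
  cross-checked end to end against an independent reimplementation on
  fixed folds.

## The synthetic benchmark

`simulateAssociations()` draws from a bipartite stochastic block model:
entities are assigned to blocks round-robin (deterministic block sizes
make test assertions simple), and cells are Bernoulli — `pIn` within
matched blocks, `pOut` elsewhere. It emulates the one feature of real
catalogues this method exploits, community structure (diseases sharing
microbe sets), at HMDAD-like shape and density; defaults are 40 × 300
with 5 blocks, `pIn = 0.3`, `pOut = 0.005`. It does **not** emulate
heavy-tailed degree distributions, study-driven ascertainment bias,
correlated annotation errors, or taxonomic nesting of microbe labels, so
synthetic recovery results demonstrate algorithmic correctness, not
clinical performance on real catalogues.

The recovery benchmark used in the tests and the acceptance script is a
40 × 60, 4-block matrix at `pIn = 0.4`, `pOut = 0.005` (roughly 250
edges): small enough that the full leak-free 5-fold CV runs in seconds on
one core, strong enough that structured data clearly separates from its
shuffled null. At the published method defaults the leak-free 5-fold AUC
on this benchmark sits around the high 0.7s, the LOOCV AUC (which removes
only one edge at a time and therefore perturbs the kernels least) in the
low-to-mid 0.8s, and the shuffled null near 0.5 — run
`scripts/acceptance.R` to regenerate the exact numbers for any seed.

## Degenerate inputs and numerical choices

* All-zero initial labels converge in one round to a zero score matrix.
* The L1 ("absolute loss") convergence criterion is the entry-wise sum of
  absolute differences; since the decay is exactly geometric, any other
  entry-wise norm changes the iteration count only by a constant offset.
* Squared distances in the kernel are computed from the Gram matrix,
  symmetrised, floored at zero and zeroed on the diagonal, so validity
  (symmetry, unit diagonal) holds exactly, not just to rounding.
* Ranking ties (equal scores) are broken by ascending column index;
  AUC ties count one half — the two conventions are consistent in the
  sense that `aucRank()` equals the trapezoidal area under `rocPoints()`
  on every input, ties included.
* Identifier normalisation: whitespace trimmed and collapsed, matching
  case-insensitive, first-seen casing preserved for display. Free-text
  synonyms and taxonomic near-duplicates are *not* merged — exact
  deduplicated counts on real exports depend on the curation state of the
  source.

## Known limitations

* GIP-kernel similarity is computed from the association table itself, so
  predictions are biased toward well-annotated diseases and microbes;
  entities with no training associations receive only neighbour-propagated
  mass under the bandwidth fallback.
* The hold-out degree bias described above means chance-level data
  evaluates slightly below 0.5; comparisons between methods should use
  identical fold structure.
* Scores are not probabilities: they scale with the converged iteration
  count and should only be compared within one run.
* LOOCV recomputes the full pipeline once per known association; on
  catalogue-scale data (hundreds of edges, a few hundred entities per
  axis) this is minutes of compute with fold-wise kernel refits, and the
  `refitSimilarity = FALSE` variant — while fast — is leaky and should
  not be the headline number.
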