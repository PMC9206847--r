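---
title: "Natural vectors with covariance components: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Natural vectors with covariance components: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natvec)
```

## The representation and its assumptions

A nucleotide sequence of length $n$ over $L = \{A, C, G, T/U\}$ is summarized
by, for each letter $k$, its count $n_k$, its mean 1-based position $\mu_k$,
and the normalized second central moment of its positions
$$D_2^k = \sum_{i=1}^{n} \frac{(i-\mu_k)^2\, w_k(s_i)}{n_k\, n},$$
where $w_k(s_i)$ indicates whether position $i$ carries letter $k$. The
covariance block adds, for each unordered pair $k \ne l$, with
$w_{kl}(s_i) = 1$ iff $s_i \in \{k, l\}$,
$$\mathrm{Cov}(k,l) =
  \sum_{i=1}^{n} \frac{(i-\mu_k)(i-\mu_l)\, w_{kl}(s_i)}{n\sqrt{n_k}\sqrt{n_l}},$$
which satisfies $\mathrm{Cov}(k,k) = D_2^k$ identically (the diagonal is
therefore never stored twice). The flattened vector has dimension
$3|L| + \binom{|L|}{2}$: 18 for DNA, 250 for the 20-letter amino-acid
alphabet, $3\cdot 4^k + \binom{4^k}{2}$ for overlapping $k$-mers.

The underlying modeling assumption is that sequences from the same
taxonomic family have similar letter-distribution geometry, so that their
vectors form tight, well-separated clusters in Euclidean space. Two
consequences worth keeping in mind:

* **Counts dominate.** $n_k$ grows linearly with sequence length while the
  moment and covariance components stay $O(n)$ and $O(n)$-bounded ratios;
  for genome-scale inputs the Euclidean distance is driven primarily by
  length and composition. This is the published convention and the default
  here (no feature scaling); `pairwise_matrix(standardize = TRUE)` is
  available for users who want per-dimension standardization, but none of
  the shipped analyses use it.
* **Position matters, order does not beyond moments.** The vector is not
  invariant under reversal or local rearrangement, but distinct sequences
  can share a vector; the map is not injective.

## Conventions for inputs the formulas do not cover

* **Positions are 1-based.** The worked example `ACGGTAGTCC`
  ($\mu_A = 3.5$) fixes this convention.
* **Ambiguity codes.** GenBank records contain IUPAC ambiguity codes. These
  are *retained* in the residue string: they occupy positions (and so count
  toward $n$ and keep every other letter's positional index faithful to the
  original molecule) but match no indicator. Deleting them would silently
  shift every downstream position. The per-sequence count of such
  characters is reported by `read_fasta()`.
* **Absent letters.** When $n_k = 0$ the formulas are undefined; the
  package sets $\mu_k = D_2^k = \mathrm{Cov}(k,\cdot) = 0$ and flags the
  letter in the vector's `absent` attribute. Zeros keep vectors finite and
  comparable across sequences; the flag preserves the information.
* **k-mer positions.** The $k$-mer generalization treats each overlapping
  window as a letter occurrence at its 1-based *start* index, with
  effective length $n - k + 1$ in every formula. Start-indexing is the
  standard k-mer convention; center-indexing would only shift all mean
  positions by $(k-1)/2$.
* **T/U.** For DNA input, U is mapped to T at load, so RNA and DNA spellings
  of the same molecule vectorize identically.

## Convex-hull disjointness

Two families intersect as convex bodies iff some convex combination of one
family's vectors equals a convex combination of the other's — an LP
feasibility problem in the combination weights with zero objective.
`hulls_disjoint()` solves it with an in-package phase-1 simplex using
Bland's anti-cycling rule, which is deterministic, finite, and exact on the
small well-conditioned systems this produces. Numerical choices:

* **Conditioning.** Natural-vector coordinates span several orders of
  magnitude (counts vs covariances). Each coordinate is divided by its
  maximum absolute value over both families before solving — an invertible
  diagonal map under which hull disjointness is invariant (verified
  property-style in the tests).
* **Tolerances.** Feasibility is declared at a phase-1 objective below
  `1e-8`; every "intersecting" verdict is re-checked against its own
  certificate (weights nonnegative, each block summing to 1, constraint
  residual below `1e-6`). A solution failing its certificate is reported as
  `solver_failure`, never silently classified: solver noise must not
  masquerade as biology.
* **Touching counts as intersecting.** A shared boundary point makes the LP
  feasible, so tangent hulls are "intersecting". The test suite checks this
  against an exact integer-arithmetic 2-D geometric oracle, including
  touching and nested configurations.
* **Minimum family size.** Hull analyses default to families with at least
  3 members (`min_size = 3`), mirroring the usual dataset filter that drops
  families too small to span a meaningful hull; it is configurable.

The separating hyperplane of a disjoint pair is computed as the hard-margin
linear maximum-margin separator (linear SVM with cost $10^8$ on the
conditioned coordinates, mapped back and normalized to $\|w\| = 1$); the
result is verified to strictly separate the inputs before it is returned.
For 2-D visualization, `project_2d()` pairs $w$ with a deterministic
orthogonal unit vector: the first standard basis vector not parallel to
$w$, orthogonalized and normalized. This choice is arbitrary among the
valid perpendiculars; determinism is the requirement.

## Distances, classification, trees

Sequence-level distance is plain Euclidean on the vectors; family-level
distance is the Hausdorff distance (the larger of the two directed
worst-case nearest-point distances). Nearest-neighbor typing breaks
distance ties by the lexicographically smallest reference id, making
results independent of reference ordering; self-matches are excluded by
sequence id (not vector equality), which gives leave-one-out semantics when
queries are drawn from the reference pool.

`upgma_tree()` implements the standard size-weighted agglomeration with two
determinism rules the generic algorithm leaves open: ties at the minimal
distance merge the pair whose index pair is lexicographically least in the
current cluster ordering, and Newick children are ordered by their smallest
descendant leaf label. Merge heights are halved distances, so the output is
ultrametric (equal root-to-leaf path lengths; recovered cophenetic
distances equal an ultrametric input exactly, to `1e-9` relative in the
tests). Branch lengths are serialized with 10 significant digits; labels
containing spaces or Newick metacharacters are single-quoted. The
implementation is cross-checked in the tests against average-linkage
`hclust`, the independent route to the same quantities.

## The legacy covariance definition

For comparison, `legacy_covariance()` implements the earlier definition
based on the two letters' position lists $A$ and $B$: with equal lengths, the
paired sample covariance of the sorted lists divided by $|A|$ and then by
the sequence length $N$; with unequal lengths, the exact average of that
quantity over *all* $\binom{|B|}{|A|}$ sorted subsets of the longer list.
The original description does not fix how subset elements are paired; the
sorted-versus-sorted pairing used here is the only reading under which the
equal-length formula is well defined, and it is applied with the subset
mean taken over the subset itself. The combinatorial enumeration is capped
(default $10^5$ subsets) with an explicit error naming the required count —
the unequal-count case grows combinatorially, which is precisely the
practical weakness the pair-indicator definition removes, so no sampling
approximation is offered.

## The synthetic-family generator

`generate_families()` emulates the one property the downstream machinery
relies on: families as clusters with controllable composition, length, and
positional structure. Letters are i.i.d. per a per-family composition, with
an optional positional bias (one letter's weight multiplied inside a stated
fractional segment, renormalized per position) so that mean-position and
covariance components — not just counts — differ between families. Each
family has its own Mersenne-Twister seed and regenerates byte-identically;
the caller's RNG state is untouched.

What it deliberately does **not** emulate: substitution processes on a
tree, indels, repeats, GC skew along replichores, or any within-family
phylogenetic structure. Passing tests on generated families therefore
demonstrate the correctness of the machinery (vectorization, LP verdicts,
typing, tree construction) under planted truth — not that real families are
separable. On real data, separability is an empirical question; published
analyses report a large but not universal fraction of disjoint family
pairs, and the report format here (pair statuses plus summary counts)
matches that use.

Default study conditions used by the test suite: three families of 8
sequences each — two 300–320 nt families differing in composition
(A-rich vs C-rich, dominant weight 0.62) and one 3,000–3,100 nt uniform
family — which plant a known nearest pair for the group tree, perfect
leave-one-out typing, and three disjoint hull pairs. Property checks run on
1,000 random sequences of length 10–2,000 (the covariance identity), 200
sequences against a naive positional oracle, and 500 random 2-D hull
instances against the geometric oracle; these sizes keep the full suite in
tens of seconds while exercising every code path.

## Known limitations

* Vector components are kept at full double precision throughout; no
  internal rounding is ever applied, so printed tables (17 significant
  digits) round-trip bit-exactly but may differ in the last digits from
  implementations that round intermediate values.
* LP verdicts on real genome-scale coordinates depend on conditioning and
  tolerances near degeneracy; the `solver_failure` status exists so such
  pairs are surfaced rather than guessed.
* The Hausdorff distance is sensitive to outlier members of a family
  (it is a worst-case distance), and the UPGMA tree inherits that
  sensitivity.
* Protein vectors use the plain 20-letter alphabet; nonstandard residues
  (B, Z, X, U, O) are treated as non-alphabet placeholders.
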