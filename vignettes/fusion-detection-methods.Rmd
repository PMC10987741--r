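---
title: "Alignment-free chromosome fusion recognition: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free chromosome fusion recognition: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Chromosome fusion — classically a Robertsonian translocation joining the
long arms of two acrocentric chromosomes — leaves one lineage with `n`
chromosomes where a related lineage has `n + 1` (human chromosome 2
versus the great apes' 2A/2B is the textbook case; swamp versus river
buffalo is another). Given two sets of chromosome-scale sequences,
`A = {a_1..a_n}` and `B = {b_1..b_{n+1}}`, `karyofuse` answers two
questions without any alignment or annotation: *which pair of B fused*,
and *which chromosome of A corresponds to each remaining chromosome of
B*.

## The embedding: k-mer natural vectors

A sequence of length `L` is read as its `m = L - k + 1` overlapping
k-mers. For every k-mer `l` we record three statistics:

* `n_l` — occurrence count;
* `mu_l` — mean of its 1-based positions (k-mer index units);
* `D2_l` — second central moment of those positions, scaled by
  `1 / (n_l * m)`.

Absent k-mers carry `n = mu = D2 = 0` by convention. The concatenation
of the three blocks over all `4^k` k-mers is the embedding
(`3 * 4^k` components, all non-negative). Vectors are stored sparsely —
only populated k-mers — and densified implicitly during cosine
computation.

The crucial property is that the embedding is (almost) algebraic under
concatenation: from the vectors of `S1` and `S2` one derives the vector
of `S1 + S2` exactly at `k = 1` — counts add, means combine as the
count-weighted mean with the second block offset by the first block's
k-mer count, and moments combine through the parallel-axis
decomposition of raw sums of squares. For `k > 1` the `k - 1` k-mers
spanning the junction are missed; on chromosome-scale (or even
kilobase-scale) inputs this perturbs the vector negligibly (the test
suite checks cosine similarity above 0.9999 between algebraic and
directly computed fused vectors once sequences exceed `10 * 4^k`
nucleotides). A reverse-strand transform completes the algebra: each
k-mer's statistics move to its reverse-complement k-mer with
`mu' = m + 1 - mu` and `D2` unchanged. Because a fused chromosome can
read in `2! * 2^2 = 8` ways (segment order times per-segment strand),
all eight candidate vectors are derived algebraically in milliseconds
rather than by re-scanning gigabases.

### Word size

The default word size for real chromosome sets is `k = 10`, small
enough to keep the `n^3 * 4^k` distance stage cheap while large enough
for chromosome-scale inputs; an information-theoretic argument places
the ideal `k` near `ceil(log4 L)`, which the CLI prints as advice
rather than enforcing. The test suite and simulator run at `k = 4..5`,
appropriate for their 3-50 kb chromosomes (`4^5 = 1024 << L`). `k` is
capped at 15 so k-mer codes stay below `2^31`.

### Ambiguity codes

Reference chromosomes contain `N` runs. Any k-mer window touching a
non-ACGT character is skipped, but position indices still advance over
it, keeping mean positions comparable across sequences. Consequently
`m` is defined as the number of k-mer *positions* (`L - k + 1` for a
directly built vector, additive under concatenation) and the counts sum
to `m` minus the skipped windows; the skipped fraction is recorded on
every vector and reported by the CLI. For clean ACGT sequences `m`
coincides with the total k-mer count.

## The decision rule

Two complementary distances separate composition from scale:

* `D1(a, b) = 1 - max cos(nv(a), nv(v))` over the strand variants of
  `b` (two for a normal chromosome, eight for a fused candidate) — pure
  k-mer-pattern dissimilarity, in `[0, 1]` because all components are
  non-negative;
* `D2(a, b) = |length(a) - length(b)|` — raw length difference;
  segment lengths add under fusion.

For one scenario (replace `b_{j1}, b_{j2}` by their fused candidate,
giving `B~` of size `n`), the pairing loss is

```
L(A, B~) = min over permutations p of
           sum_i  N(D1(a_i, b~_{p_i})) + N(D2(a_i, b~_{p_i}))
```

where `N` min-max normalizes each distance within its row (the `n`
candidates competing for `a_i`), balancing the two scales. The
minimization is an assignment problem solved exactly with the
Kuhn-Munkres method. The scenario with the smallest loss names the
fused pair; its permutation is the chromosome correspondence; the gap
to the runner-up is a reliability indicator (a gap comparable to the
spread of non-optimal losses is flagged as unreliable).

Enumerating scenarios costs `choose(n+1, 2)` loss evaluations (253 for
23 chromosomes). All raw `D1`/`D2` values are computed once; each
scenario only re-normalizes its own `n x n` matrix and solves one
assignment, for an overall complexity of
`O(n l + n^3 4^k + n^5)`.

### Numerical and design choices

* **Normalization pool.** `N` is taken row-wise *within the current
  scenario's* candidate set — the reading that binds the pool to
  `D_l(a_i, ·)` inside one loss evaluation. A global pool across
  scenarios is a conceivable alternative; it would rescale losses but
  the per-scenario reading keeps every scenario's matrix
  self-normalized and is what this package implements.
* **Degenerate pools** (all row values equal, e.g. `n = 1`) normalize
  to 0: a constant row cannot rank candidates, and any constant
  preserves the argmin.
* **Fused candidates** use only their eight representations in `D1`;
  no extra reverse complement is applied on top since the eight already
  cover both strands.
* **Ties.** The assignment solver returns the lexicographically
  smallest optimal permutation (resolved by re-solving reduced
  problems), and scenario ties are broken by lexicographic pair order
  with a warning — equal optimal and sub-optimal losses are precisely
  the unreliable regime.
* **Floating point.** `D2_l`'s `1/(n_l m)` scaling is applied during
  aggregation so chromosome-scale squared positions (~1e16-1e18) stay
  well inside double range.

## The synthetic-data generator

`make_fusion_dataset()` emulates the planted-fusion experiment on which
the method's accuracy is quantified: draw `n + 1` independent random
chromosomes (set B), fuse a random pair in random order and strand
orientation into one member of set A, carry the others over, and record
the truth. Defaults are the desk-scale study conditions used by the
test suite and the acceptance script: 9 chromosomes in B (`n = 8`,
giving 36 scenarios), lengths 20-50 kb, 42% GC (typical mammalian
composition), 0.5% substitutions plus 0.05% single-base insertions and
deletions between the sets, and a fair-coin strand flip per set-A
member. Every set-A member — including the fused product — passes
through the same mutation channel: sequencing noise does not spare the
fused chromosome, and at rate 0 the fused member is still the exact
concatenation.

What random sequences *do* reproduce is the discriminative signal the
method actually uses: independent chromosomes differ in k-mer
composition and length, and a fused product inherits its segments'
statistics almost exactly. What they do **not** reproduce is the
repeat structure, centromeres/telomeres, segmental duplications and
inter-chromosomal homology of real genomes, all of which raise optimal
losses and compress the optimal/sub-optimal gap relative to synthetic
data. Passing tests therefore demonstrate correctness of the machinery and
robustness to noise, order, and strand — not performance on real
repeat-rich genomes, for which the CLI accepts real FASTA input at
`k = 10`.

Fusion orientation is deliberately excluded from truth scoring: all
eight readings describe the same molecule, so only the fused pair and
the correspondence are scored.

## Multidimensional scaling

For visualisation, within-set distances reuse the normalized two-part
distance with the set playing both roles, symmetrized as
`(M + t(M))/2` (the arithmetic mean is the canonical symmetrization and
preserves the zero diagonal; row-normalization makes the directed
matrix asymmetric). The 2-D embedding minimizes the raw stress
`sum_{i != j} (d_ij - |x_i - x_j|)^2` by SMACOF majorization (iterated
Guttman transform), which guarantees a non-increasing stress sequence —
a property the tests assert directly. Four seeded random starts are run
(tolerance `1e-9` relative stress change, at most 1000 iterations each)
and the best kept; the embedding is arbitrary up to rotation,
reflection and translation, so only inter-point distances are
meaningful.

## Problem sizes used by the checks

The packaged checks run at deliberately modest scale chosen to exercise
every code path: oracle comparisons on 100-2000 nt sequences at
`k <= 5` (plus ~11 kb pairs for the `k = 5` cosine regime), 200 random
assignment instances up to 7x7 against exhaustive enumeration, 20
zero-noise and 50 noisy planted-fusion datasets at `n = 8`, 20-50 kb,
`k = 5`, and 5-7 point MDS configurations. Real chromosome sets (tens
of members, 1e7-1e9 nt) are supported through the same functions; the
`complexity_guard()` helper estimates the operation count before a
large run.

## Known limitations

* One fusion of exactly two segments per comparison; multiple
  simultaneous fusions or >2-segment fusions would require enumerating
  `s! 2^s` representations and a larger scenario space.
* Non-fusion structural variation (repeats, reciprocal translocations,
  large inversions) is invisible to the loss or can blur it — a small
  optimal/sub-optimal gap is the warning sign.
* `D2` assumes lengths are meaningful; heavily gapped assemblies
  distort it.
* The min-max normalization makes losses comparable within a run, not
  across datasets.
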