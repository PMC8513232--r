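---
title: "Rearrangement distances with repeated genes and intergenic regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rearrangement distances with repeated genes and intergenic regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igdist)
```

## The model

A genome is modelled as an alternating sequence of `n` genes and `n - 1`
intergenic regions, written 𝒢 = (S, Ŝ): `S` is a string of gene labels
(a label may occur several times — a *gene family*), and `Ŝ` records
only the *size* of each intergenic region in nucleotides, not its
sequence content. Orientation of genes is not modelled, and a genome is
a single linear chromosome. Real genomes also begin and end with
intergenic material, so before comparison both genomes are *capped*:
one artificial gene is appended at each end, the same pair of labels for
both genomes, which makes the pair *co-tailed* (equal first and last
genes).

Two genomes are *balanced* when they carry the same multiset of gene
labels and the same total intergenic size. Balance is exactly the
condition under which conservative rearrangements can transform one
genome into the other:

* an **intergenic transposition** τ(i,j,k)(x,y,z), `2 ≤ i < j < k ≤ n`,
  exchanges the consecutive segments `S[i..j-1]` and `S[j..k-1]`; the
  three affected regions are cut at offsets x, y, z and the pieces are
  recombined around the moved segments;
* an **intergenic reversal** ρ(i,j)(x,y), `2 ≤ i < j ≤ n-1`, reverses
  `S[i..j]` together with its internal regions; the flanking regions
  are cut at x and y.

The distances d_IT, d_IR and d_IRT are the minimum numbers of such
operations under the transposition, reversal and mixed models. All
three are NP-hard, which motivates bounds and approximations.

## Partitions as the computational backbone

A *direct intergenic partition* of balanced genomes (𝒢, ℋ) removes a
set of intergenic regions (*breakpoints*) from each genome so that the
resulting block sequences are matched by a bijection with exact equality
of blocks — gene labels *and* internal intergenic sizes. A *reverse*
partition allows a matched block to be reversed. The *cost* is the
number of breakpoints (blocks minus one). Finding a minimum-cost
partition (the MCISP/RMCISP problems) is NP-hard, but:

* any sequence of operations transforming 𝒢 into ℋ induces an
  assignment whose minimal partition it must dismantle, and one
  transposition can merge at most three block pairs and one reversal at
  most two — hence the lower bounds ⌈cost/3⌉ (transpositions, mixed)
  and ⌈cost/2⌉ (reversals) in `partition_lower_bound()`;
* conversely, given any orthologous assignment ξ (a label-preserving
  bijection between gene positions) with induced minimal partition cost
  `c`, the sorters construct certified sequences of at most `c + 1`
  transpositions, `2c` reversals, or `⌈1.5c⌉` mixed operations.

`validate_partition()` checks validity by two independent routes — an
explicit block matching, and the criterion that every subgenome occurs
equally often within the source blocks and within the target blocks —
and raises an error if they ever disagree; on every tested family they
agree, as the two conditions are provably equivalent.

## The 2k-approximation

`mcisp_partition()` / `rmcisp_partition()` implement a greedy
breakpoint-insertion scheme. Define the *weight* of a subgenome `X` as
its occurrence count within the current source blocks minus that within
the current target blocks (`subgenome_weight()`; occurrences compare
labels and internal sizes, and in the reverse variant both orientations
count, a palindromic window once). A pair of block sequences is a valid
partition exactly when every weight is zero. The algorithm repeatedly
selects a containment-minimal subgenome of non-zero weight and cuts one
surplus occurrence, until no non-zero weight remains.

Key choices, all deterministic:

* **Selection order.** Among non-zero-weight subgenomes, the smallest
  under (gene count, label sequence, intergenic sequence) is chosen.
  Since a containment-minimal element always exists among the smallest,
  this is the least element of the current witness set; it also
  reproduces the worked trace shipped in the test suite.
* **Cut placement.** Each witness-set entry `X` carries a designated
  offset `break(X)` — its first internal region for entries of the
  initial witness set, or, for entries appearing mid-run, the offset of
  the chronologically first breakpoint inserted inside an occurrence of
  `X` in the original genomes. The cut is placed at that offset inside
  the leftmost surplus occurrence (mirrored for a reversed occurrence),
  which makes every inserted breakpoint equivalent (congruent, in
  reverse mode) to `break(X)` for some initial witness `X`.
* **Guarantee.** Each gene occurs at most `k` times per genome, so at
  most `2k` breakpoints can be equivalent to any one `break(X)`; the
  cost is therefore at most `2k·|T_min|`, and since every valid
  partition must cut at least one occurrence of each witness, at most
  `2k` times the optimum. The test suite checks the stronger
  `cost ≤ 2k·opt` form against the exhaustive oracle on the
  small-instance family.

The witness set is recomputed from scratch each iteration by tabulating
all block windows (`O(n³)` per iteration); the known suffix-tree
acceleration is deliberately not implemented — at the package's intended
scales (up to a few hundred genes) the plain tabulation is sufficient
and much simpler to audit.

## Sorting constructions

`sort_by_transpositions()` follows a three-case loop over the breakpoint
classification of the current induced partition (`soft` when the
assigned neighbours are not consecutive in the target; `hard` otherwise,
`overcharged`/`undercharged` by size). Two or more overcharged
breakpoints are discharged pairwise by a two-transposition
redistribution (`redistribute_three()`, which provably realizes *any*
conserving redistribution of three regions and is verified by
application); a qualifying soft breakpoint is removed by one
transposition whose cuts are chosen, among a small candidate set
evaluated by application, to create as few overcharged breakpoints as
possible; a single leftover overcharged breakpoint is discharged against
an undercharged or soft partner. Every path removes at least one
breakpoint per operation except a single slack step, giving the
`cost + 1` bound, which is asserted at run time.

`sort_by_reversals()` and the mixed sorter place the target's blocks
left to right. A block present in the opposite orientation is spliced
into place by one reversal; one in the needed orientation by two
reversals (or a single transposition in the mixed model); junction sizes
are set exactly through the operation's cut parameters. When the
regions cut by a placement cannot supply the junction target, free
nucleotides are pooled by gather reversals or moved by *reversal pairs*
— two reversals over the same span, which net-redistribute between the
two cut regions while restoring every gene and every other region (so
the span may freely cross block boundaries). Adjacent regions exchange
content through a borrowed, exactly restored intermediate region, or by
a four-reversal three-gene rotation when no intermediate exists. The
engine is run under several greedy preferences (flip-first vs
pool-sweeping placements, two gather policies) and with the
order-preserving per-label assignment substituted when it induces fewer
breakpoints than the supplied one — any valid assignment yields a
sequence transforming 𝒢 into ℋ, so the cheaper one may be used while
the bound is still stated against the supplied assignment. On tiny
instances a breadth-first search supplies an exact sequence if the
greedy exceeds its bound. Violations that survive all of this raise a
hard error rather than returning an out-of-bound sequence.

Two genuine degeneracies are worth knowing about:

* on size-4 genomes the only legal reversal swaps the middle gene pair,
  so the middle intergenic region is invariant: pairs that differ there
  are *unreachable* under the reversal model (`bfs_exact_distance()`
  confirms this), and `sort_by_reversals()` reports them as unsortable —
  the 2·cost guarantee implicitly assumes genomes large enough for the
  repair moves to exist;
* for adversarially fragmented nucleotide distributions (many
  single-gene blocks with large, scattered junction deficits) the greedy
  placement can exceed its bound on instances too large for the BFS
  fallback; this is rare (well under 1% of harsh random instances,
  unobserved under the simulation study's conditions) and is reported as
  an error, never as a silent over-long result.

## Assignments and distance estimation

`sample_assignment()` draws uniform orthologous assignments: per label
class without a partition, or — given a partition — a uniform matching
between blocks within each equality/congruence class followed by
positional gene mapping (reversed for reversed block matches).
`estimate_distance()` sorts the pair under each sampled assignment and
reports the minimum and mean sequence lengths; every length is certified
by re-applying the operations and comparing with the target genome
bit-exactly. Randomness comes from R's global generator; seed with
`set.seed()` (the command-line interface and the experiment pipeline
expose explicit `seed` parameters).

## The simulator

`build_database()` emulates a controlled evolution experiment: the
source genome has `n` genes drawn uniformly from an `m`-letter alphabet
and intergenic sizes uniform on `0..100` (inclusive); the target is the
source after `o` random operations (uniform indices, then uniform cuts
given the current sizes; the mixed model interleaves ⌊o/2⌋ reversals and
⌈o/2⌉ transpositions in uniformly shuffled order); both genomes are then
capped with the same fresh labels and the same pair of cap gaps drawn
uniformly on the same range — equal gaps keep the pair balanced, a
choice the package makes because nothing in the protocol pins the cap
sizes down. What the simulator does *not* emulate: real gene-family
size distributions, length-dependent rearrangement rates, or
non-conservative events (insertions, deletions); passing tests therefore
demonstrate correctness of the machinery under the stated generative
model, not biological realism.

`run_experiment()` reproduces the benchmark design at configurable
scale: for each pair, distances are estimated over assignments sampled
with and without the partition, and per-pair minima and means are
aggregated into min/avg/max summaries. The package's test suite runs
this at a reduced scale (30 genes, alphabet 5, 10 operations, 10 pairs,
20 assignments, fixed seed — sizes chosen to keep the default test run
short while leaving the directional contrast far from the noise floor)
and checks the directional finding: partition-guided estimates are
lower than unconstrained ones for all three models. Full-scale runs
(100 genes, 100 pairs, 100 assignments) use the same code path.

## Numerical and engineering choices

* All indices are 1-based, matching the field's conventions; intergenic
  region `i` lies between genes `i` and `i + 1`.
* Genome equality is exact integer equality of sizes; labels are opaque
  tokens. Sort keys zero-pad integers so byte order equals numeric
  order, independent of locale.
* `⌈1.5·cost⌉` is used for the mixed bound at odd costs.
* The exhaustive partition oracle enumerates source breakpoint subsets
  in increasing cardinality with a block-signature index over target
  subsets, guarded to 12 genes; the BFS distance oracle is guarded to 6
  genes and intergenic sum 6 by default (both guards overridable).
* Every sorter result and every estimate is verified by application
  before being reported; internal invariant violations raise errors
  naming the violated bound.

## Known limitations

* The approximation guarantee is `2k` — weak for large gene families;
  the practical quality observed in the experiments is far better, but
  no stronger guarantee is claimed.
* Exact distances are available only at oracle scales; at realistic
  sizes the package reports certified upper bounds and partition-based
  lower bounds.
* Unbalanced genomes (unequal gene content or intergenic totals) are
  rejected; modelling insertions/deletions is out of scope.
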