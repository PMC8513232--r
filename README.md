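# igdist

Rearrangement distances between genomes that carry **repeated genes**
and **intergenic regions**.

When two genomes are compared by the number of rearrangement events
(transpositions, reversals) needed to transform one into the other, most
classical tooling assumes every gene occurs once and ignores the DNA
between genes. `igdist` works with the richer representation
𝒢 = (S, Ŝ): a string *S* of gene labels (duplicates allowed) together
with the list Ŝ of intergenic region sizes in nucleotides. An
*intergenic transposition* τ(i,j,k)(x,y,z) exchanges two consecutive
gene segments and cuts the three affected intergenic regions at offsets
x, y, z; an *intergenic reversal* ρ(i,j)(x,y) reverses a segment and
cuts the two flanking regions. The distances d_IT, d_IR and d_IRT are
the minimum numbers of such operations; all three problems are NP-hard.

The package is built around the **minimum common intergenic string
partition** problems (MCISP and its reverse variant RMCISP): split both
genomes into the fewest blocks such that the blocks of one genome can be
reordered (and, in the reverse variant, individually reversed) to yield
the blocks of the other, where blocks must match in both gene labels and
internal intergenic sizes. The partition cost bounds the distances from
below (cost/3 for transpositions and mixed models, cost/2 for
reversals), and constructive sorting procedures achieve at most cost+1
transpositions, 2·cost reversals, or ⌈1.5·cost⌉ mixed operations for the
minimal partition induced by an orthologous assignment. MCISP/RMCISP are
approximated greedily within a factor **2k**, where k is the maximum
number of copies of any gene: repeatedly find the smallest subgenome
whose occurrence counts differ between the two genomes' current blocks
and cut one surplus occurrence.

## What is in the package

* genome construction, capping, balance/congruence predicates,
  subgenome occurrence counting (`genome()`, `cap_genome()`,
  `is_balanced()`, `count_occurrences()`, ...);
* intergenic transpositions and reversals with exact nucleotide
  bookkeeping (`apply_transposition()`, `apply_reversal()`,
  `redistribute_three()`);
* the 2k-approximation for MCISP/RMCISP (`mcisp_partition()`,
  `rmcisp_partition()`, `compute_tmin()`), assignment-induced partitions
  and breakpoint classification (`induced_partition()`,
  `classify_breakpoints()`), plus an exhaustive small-instance oracle
  (`brute_force_min_partition()`);
* constructive sorters meeting the partition bounds
  (`sort_by_transpositions()`, `sort_by_reversals()`,
  `sort_by_reversals_and_transpositions()`), partition lower bounds and
  an exact BFS oracle (`partition_lower_bound()`,
  `bfs_exact_distance()`);
* distance estimation over uniformly sampled orthologous assignments
  (`sample_assignment()`, `estimate_distance()`) and a simulation
  pipeline (`generate_source_genome()`, `run_experiment()`);
* a command-line interface in `exec/igdist` and a two-line plain-text
  genome file format (`read_genome()` / `write_genome()`).

## Worked example

```r
library(igdist)

g <- genome(c("I","B","A","B","C","B","C","F"), c(1, 3, 2, 3, 1, 3, 2))
h <- genome(c("I","B","C","A","B","B","C","F"), c(1, 3, 0, 2, 4, 3, 2))

p <- mcisp_partition(g, h)
print(p)
#> direct intergenic partition, cost 4
#>   S: ([I],[]) ([B],[]) ([A],[]) ([B C],[3]) ([B C F],[3 2])
#>   P: ([I],[]) ([B C],[3]) ([A],[]) ([B],[]) ([B C F],[3 2])
attr(p, "k"); attr(p, "n_tmin")
#> [1] 3
#> [1] 6
```

The two genomes share the gene multiset {I, B×3, A, C×2, F} and a total
of 15 intergenic nucleotides. The greedy 2k-approximation cuts four
breakpoints, splitting each genome into five blocks that match one to
one (including their internal intergenic sizes); the guarantee here is
cost ≤ 2·k·|T_min| = 2·3·6 = 36, and the exhaustive oracle confirms no
partition with fewer than 4 breakpoints exists for this pair.

Distance estimation on a simulated pair:

```r
set.seed(1)
src <- generate_source_genome(30, m = 5, max_intergenic = 100)
tgt <- generate_target_genome(src, "reversal", o = 10)
g <- cap_genome(src, "S0", "T0", 3, 5)
h <- cap_genome(tgt, "S0", "T0", 3, 5)
estimate_distance(g, h, "reversal", n_assignments = 20, use_partition = TRUE)
#> distance estimate (reversal, with partition): min 23, avg 25.95 over 20 assignments
estimate_distance(g, h, "reversal", n_assignments = 20, use_partition = FALSE)
#> distance estimate (reversal, without partition): min 35, avg 35.00 over 20 assignments
```

Every reported distance is certified: the operation sequence is
re-applied and must reproduce the target genome exactly. Assignments
consistent with the approximate partition give visibly lower estimates
than unconstrained per-label assignments — the package's headline
empirical finding.

## Command line

```sh
exec/igdist partition --mode direct inst/extdata/ex3_G.txt inst/extdata/ex3_H.txt
exec/igdist distance --model rev --assignments 20 --seed 1 G.txt H.txt
exec/igdist oracle --min-partition --mode direct inst/extdata/ex1_G.txt inst/extdata/ex1_H.txt
```
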