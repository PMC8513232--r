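# Assignment realized by applying a known operation: the gene moved from
# position p sits at position t afterwards, so xi maps p to t.
realized_assignment <- function(n, perm) {
  xi <- integer(n)
  xi[perm] <- seq_len(n)
  xi
}

test_that("a single worked transposition is recovered within the bound", {
  g <- fig4_source()
  h <- apply_transposition(g, transposition(2, 4, 6, 2, 2, 0))
  xi <- realized_assignment(6, igdist:::transposition_perm(6, 2, 4, 6))
  res <- sort_by_transpositions(g, h, xi)
  expect_gte(length(res$operations), 1)
  expect_lte(length(res$operations), res$partition_cost + 1)
  expect_equal(apply_ops(g, res$operations), h)
})

test_that("a single worked reversal is recovered within the bound", {
  g <- fig4_source()
  h <- apply_reversal(g, reversal(2, 4, 3, 1))
  xi <- realized_assignment(6, igdist:::reversal_perm(6, 2, 4))
  res <- sort_by_reversals(g, h, xi)
  expect_equal(apply_ops(g, res$operations), h)
  expect_lte(length(res$operations), 2 * res$partition_cost)
  mix <- sort_by_reversals_and_transpositions(g, h, xi)
  expect_equal(apply_ops(g, mix$operations), h)
  expect_lte(length(mix$operations), ceiling(1.5 * mix$partition_cost))
})

test_that("equal genomes sort with the empty sequence", {
  g <- fig1_genome()
  id <- seq_len(genome_size(g))
  for (model in c("transposition", "reversal", "mixed")) {
    res <- sorter_for(model)(g, g, id)
    expect_length(res$operations, 0)
    expect_equal(res$partition_cost, 0)
  }
})

test_that("pure nucleotide imbalance is fixed by one redistribution pair", {
  g <- genome(c("A","B","C","D"), c(2, 0, 0))
  h <- genome(c("A","B","C","D"), c(0, 0, 2))
  res <- sort_by_transpositions(g, h, 1:4)
  expect_length(res$operations, 2)
  expect_equal(apply_ops(g, res$operations), h)
})

test_that("the soft-breakpoint move strictly reduces the induced cost", {
  g <- genome(c("A","C","B","D"), c(2, 0, 0))
  h <- genome(c("A","B","C","D"), c(0, 0, 2))
  xi <- c(1L, 3L, 2L, 4L)
  before <- partition_cost(induced_partition(g, h, xi, "direct"))
  op <- remove_soft_breakpoint(g, h, xi)
  g2 <- apply_transposition(g, op)
  xi2 <- igdist:::update_xi(xi, 4, op)
  after <- partition_cost(induced_partition(g2, h, xi2, "direct"))
  expect_lt(after, before)
  # and on randomized reachable instances
  set.seed(61)
  tried <- 0
  for (i in 1:40) {
    pr <- random_operation_pair(n_core = 6, o = 2, model = "transposition")
    xi <- sample_assignment(pr$g, pr$h)
    p <- induced_partition(pr$g, pr$h, xi, "direct")
    cls <- classify_breakpoints(pr$g, pr$h, xi, p)
    qual <- cls$position[cls$kind == "soft" &
      pr$g$intergenic[cls$position] >=
        vapply(cls$position, function(t) {
          v <- igdist:::xi_region(pr$h, xi, t)
          if (is.finite(v)) v else Inf
        }, numeric(1))]
    if (length(qual) == 0) next
    tried <- tried + 1
    op <- remove_soft_breakpoint(pr$g, pr$h, xi)
    g2 <- apply_transposition(pr$g, op)
    xi2 <- igdist:::update_xi(xi, genome_size(pr$g), op)
    expect_lt(partition_cost(induced_partition(g2, pr$h, xi2, "direct")),
              partition_cost(p))
  }
  expect_gt(tried, 5)
})

test_that("remove_soft_breakpoint refuses when no qualifying breakpoint exists", {
  g <- genome(c("A","B","C","D"), c(1, 1, 1))
  expect_error(remove_soft_breakpoint(g, g, 1:4), "no soft breakpoint")
})

test_that("sorters transform and respect their bounds on random instances", {
  set.seed(77)
  for (i in 1:30) {
    pr <- random_operation_pair(n_core = sample(4:8, 1), o = sample(1:3, 1),
                                model = sample(c("transposition", "reversal",
                                                 "mixed"), 1))
    for (model in c("transposition", "reversal", "mixed")) {
      xi <- sample_assignment(pr$g, pr$h)
      res <- sorter_for(model)(pr$g, pr$h, xi)
      expect_equal(apply_ops(pr$g, res$operations), pr$h)
      expect_lte(length(res$operations), res$bound)
    }
  }
})

test_that("the mixed sorter never does worse than reversals alone", {
  set.seed(88)
  for (i in 1:10) {
    pr <- random_operation_pair(n_core = 5, o = 2, model = "reversal")
    xi <- sample_assignment(pr$g, pr$h)
    rev_only <- sort_by_reversals(pr$g, pr$h, xi)
    mixed <- sort_by_reversals_and_transpositions(pr$g, pr$h, xi)
    expect_lte(length(mixed$operations), length(rev_only$operations))
  }
})

test_that("sorters reject non-sortable inputs explicitly", {
  g <- genome(c("A","B","C"), c(1, 0))
  h <- genome(c("A","B","C"), c(0, 1))
  expect_error(sort_by_transpositions(g, h, 1:3), "unsortable")
  expect_error(sort_by_reversals(g, h, 1:3), "unsortable")
  expect_error(sort_by_transpositions(genome(c("A","B"), 1),
                                      genome(c("B","A"), 1), c(2L, 1L)),
               "co-tail")
})

test_that("partition lower bounds match the worked exhaustive minima", {
  p1 <- ex1_pair()
  expect_equal(partition_lower_bound(p1$g, p1$h, "transposition"), 1)
  p2 <- ex2_pair()
  expect_equal(partition_lower_bound(p2$g, p2$h, "reversal"), 2)
  expect_equal(partition_lower_bound(p2$g, p2$h, "mixed"), 1)
  g <- fig1_genome()
  expect_equal(partition_lower_bound(g, g, "transposition"), 0)
})

test_that("BFS distance certifies the worked single-operation pairs", {
  g <- genome(c("U","a","b","c","V"), c(1, 1, 1, 1))
  h1 <- apply_transposition(g, transposition(2, 3, 5, 1, 0, 1))
  expect_equal(bfs_exact_distance(g, h1, "transposition", max_sum = 10), 1)
  h2 <- apply_reversal(g, reversal(2, 4, 0, 1))
  expect_equal(bfs_exact_distance(g, h2, "reversal", max_sum = 10), 1)
  expect_equal(bfs_exact_distance(g, g, "mixed", max_sum = 10), 0)
  expect_error(bfs_exact_distance(fig1_genome(), fig1_genome(), "reversal"),
               "too large")
})

test_that("the reversal model cannot cross a pinned junction on size-4 genomes", {
  # with four genes the only legal reversal swaps the middle pair, so the
  # middle intergenic region is invariant; such pairs are unreachable and
  # the sorter reports them rather than looping
  g <- genome(c("U","a","b","V"), c(1, 0, 0))
  h <- genome(c("U","a","b","V"), c(0, 1, 0))
  expect_error(bfs_exact_distance(g, h, "reversal"), "unreachable")
  expect_error(sort_by_reversals(g, h, 1:4), "unsortable")
  # transpositions mix all three regions and do reach the target (two
  # operations: the segment swap must be swapped back)
  expect_equal(bfs_exact_distance(g, h, "transposition"), 2)
  res <- sort_by_transpositions(g, h, 1:4)
  expect_equal(apply_ops(g, res$operations), h)
})

test_that("estimated distances are certified and ordered", {
  set.seed(303)
  pr <- random_operation_pair(n_core = 6, o = 2, model = "transposition")
  est <- estimate_distance(pr$g, pr$h, "transposition", n_assignments = 8,
                           use_partition = TRUE)
  expect_lte(est$min_distance, est$avg_distance)
  expect_equal(est$n_assignments, 8)
  g <- fig1_genome()
  est0 <- estimate_distance(g, g, "reversal", n_assignments = 3)
  expect_equal(est0$min_distance, 0)
  expect_equal(est0$avg_distance, 0)
})
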