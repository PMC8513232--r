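test_that("subgenome weights reproduce the worked occurrence counts", {
  p <- ex3_pair()
  expect_equal(subgenome_weight(p$g, p$h, genome(c("C","B"), 1), "direct"), 1)
  expect_equal(subgenome_weight(p$g, p$g, genome(c("C","B"), 1), "direct"), 0)
  expect_equal(subgenome_weight(p$g, p$h, genome(c("B","C"), 3), "direct"), 0)
})

test_that("the containment-minimal witness set matches the worked trace", {
  p <- ex3_pair()
  tm <- compute_tmin(p$g, p$h, "direct")
  got <- lapply(tm, function(e) e$genome)
  want <- list(genome(c("B","A"), 3), genome(c("A","B","C"), c(2, 3)),
               genome(c("C","B"), 1), genome(c("I","B","C"), c(1, 3)),
               genome(c("C","A"), 0), genome(c("B","B"), 4))
  expect_equal(length(got), 6)
  key <- function(g) paste(paste(g$genes, collapse = " "),
                           paste(g$intergenic, collapse = " "))
  expect_setequal(vapply(got, key, character(1)),
                  vapply(want, key, character(1)))
  # an equally-frequent subgenome is excluded
  expect_false(key(genome(c("A","B"), 2)) %in% vapply(got, key, character(1)))
  # identical genomes leave nothing to cut
  expect_length(compute_tmin(p$g, p$g, "direct"), 0)
  expect_true(all(vapply(tm, function(e) e$weight != 0, logical(1))))
})

test_that("the 2k-approximation reproduces the worked final blocks", {
  p <- ex3_pair()
  part <- mcisp_partition(p$g, p$h)
  expect_true(validate_partition(part))
  expect_equal(partition_cost(part), 4)
  bs <- partition_blocks(part, "source")
  bp <- partition_blocks(part, "target")
  fmt <- function(blocks) vapply(blocks, function(b)
    paste(b$genes, collapse = " "), character(1))
  expect_equal(fmt(bs), c("I", "B", "A", "B C", "B C F"))
  expect_equal(fmt(bp), c("I", "B C", "A", "B", "B C F"))
  expect_equal(bs[[4]]$intergenic, 3L)
  expect_equal(bs[[5]]$intergenic, c(3L, 2L))
  # printed guarantee: cost <= 2 k |T_min|
  expect_lte(partition_cost(part), 2 * attr(part, "k") * attr(part, "n_tmin"))
  expect_equal(attr(part, "k"), 3)
  expect_equal(attr(part, "n_tmin"), 6)
})

test_that("identical and mirrored genomes partition at zero cost", {
  g <- fig1_genome()
  expect_equal(partition_cost(mcisp_partition(g, g)), 0)
  expect_equal(partition_cost(rmcisp_partition(g, g)), 0)
  expect_equal(partition_cost(rmcisp_partition(g, reverse_genome(g))), 0)
})

test_that("validate_partition accepts the printed partitions and rejects noise", {
  p1 <- ex1_pair()
  printed1 <- new_partition(p1$g, p1$h, c(3, 4, 6), c(1, 3, 6), "direct")
  expect_true(validate_partition(printed1))
  perturbed <- new_partition(p1$g,
                             genome(p1$h$genes, c(3, 3, 1, 1, 2, 2, 2)),
                             c(3, 4, 6), c(1, 3, 6), "direct")
  expect_false(validate_partition(perturbed))

  p2 <- ex2_pair()
  printed2r <- new_partition(p2$g, p2$h, c(3, 4, 7), c(1, 4, 7), "reverse")
  printed2d <- new_partition(p2$g, p2$h, c(3, 4, 7), c(1, 4, 7), "direct")
  expect_true(validate_partition(printed2r))
  expect_false(validate_partition(printed2d))
})

test_that("the exhaustive oracle finds the printed minimum costs", {
  p1 <- ex1_pair()
  expect_equal(partition_cost(brute_force_min_partition(p1$g, p1$h, "direct")), 3)
  p2 <- ex2_pair()
  expect_equal(partition_cost(brute_force_min_partition(p2$g, p2$h, "reverse")), 3)
  g <- fig1_genome()
  expect_equal(partition_cost(brute_force_min_partition(g, g, "direct")), 0)
  big <- genome(rep(c("a", "b"), 8), rep(0, 15))
  expect_error(brute_force_min_partition(big, big), "too large")
})

test_that("assignment-induced partitions match the worked classification", {
  p1 <- ex1_pair()
  # positional assignment of the worked example: blocks matched as
  # [A E B] -> target block 3, [C] -> 1, first [D E] -> 2, second -> 4
  xi <- c(4L, 5L, 6L, 1L, 2L, 3L, 7L, 8L)
  part <- induced_partition(p1$g, p1$h, xi, "direct")
  expect_equal(part$source_breakpoints, c(3L, 4L, 6L))
  expect_equal(part$target_breakpoints, c(1L, 3L, 6L))
  expect_equal(partition_cost(part), 3)
  expect_true(validate_partition(part))

  cls <- classify_breakpoints(p1$g, p1$h, xi, part)
  expect_equal(cls$kind, c("soft", "hard", "soft"))
  expect_equal(cls$charge[cls$position == 4], "undercharged")
  expect_equal(sum(cls$kind == "soft"), 2)

  # identity assignment on equal genomes: no breakpoints
  g <- fig1_genome()
  id <- seq_len(genome_size(g))
  expect_equal(partition_cost(induced_partition(g, g, id, "direct")), 0)
  expect_equal(nrow(classify_breakpoints(g, g, id,
                                         induced_partition(g, g, id, "direct"))), 0)

  # both adjacencies kept but sizes differ: two hard breakpoints
  ga <- genome(c("A","B","C"), c(0, 2))
  hb <- genome(c("A","B","C"), c(1, 1))
  pa <- induced_partition(ga, hb, 1:3, "direct")
  expect_equal(pa$source_breakpoints, c(1L, 2L))
  ca <- classify_breakpoints(ga, hb, 1:3, pa)
  expect_equal(ca$charge, c("undercharged", "overcharged"))
})

test_that("reverse-mode induced partitions split on orientation flips", {
  # g = identity-ish, h reversed core: single reversed block
  g <- genome(c("U","a","b","c","V"), c(1, 2, 3, 4))
  h <- genome(c("U","c","b","a","V"), c(1, 3, 2, 4))
  xi <- c(1L, 4L, 3L, 2L, 5L)
  pr <- induced_partition(g, h, xi, "reverse")
  expect_equal(partition_cost(pr), 2)
  expect_true(validate_partition(pr))
  # in direct mode the same assignment cuts the whole reversed run apart
  pd <- induced_partition(g, h, xi, "direct")
  expect_gt(partition_cost(pd), partition_cost(pr))
})

test_that("example-one worked partition is induced by the block assignment", {
  p2 <- ex2_pair()
  # worked reverse partition: source blocks [A E B][C][A E D][E D]
  # matched to target blocks [A E B] (forward), [C], [D E A] (reversed)
  # and [D E] (reversed)
  xi <- c(5L, 6L, 7L, 1L, 4L, 3L, 2L, 9L, 8L)
  pr <- induced_partition(p2$g, p2$h, xi, "reverse")
  expect_equal(partition_cost(pr), 3)
  expect_true(validate_partition(pr))
  expect_equal(pr$source_breakpoints, c(3L, 4L, 7L))
})

test_that("induced partitions are minimal: merging adjacent blocks breaks validity", {
  set.seed(42)
  for (i in 1:15) {
    pr <- random_cotailed_pair()
    xi <- sample_assignment(pr$g, pr$h)
    for (mode in c("direct", "reverse")) {
      part <- induced_partition(pr$g, pr$h, xi, mode)
      expect_true(validate_partition(part))
      expect_equal(length(part$source_breakpoints),
                   length(part$target_breakpoints))
      bps <- part$source_breakpoints
      if (length(bps) >= 1 && mode == "direct") {
        # dropping one source cut must break the direct block matching
        for (drop in bps) {
          smaller <- new_partition(pr$g, pr$h, setdiff(bps, drop),
                                   part$target_breakpoints, mode)
          expect_false(validate_partition(smaller))
        }
      }
    }
  }
})

test_that("approximate partitions validate and respect 2k times the optimum", {
  set.seed(99)
  for (i in 1:25) {
    pr <- random_cotailed_pair(n_core = sample(2:4, 1))
    k <- max_occ(pr$g)
    pd <- mcisp_partition(pr$g, pr$h)
    expect_true(validate_partition(pd))
    opt_d <- partition_cost(brute_force_min_partition(pr$g, pr$h, "direct"))
    expect_lte(partition_cost(pd), 2 * k * max(opt_d, 0) + 0)
    pv <- rmcisp_partition(pr$g, pr$h)
    expect_true(validate_partition(pv))
    opt_r <- partition_cost(brute_force_min_partition(pr$g, pr$h, "reverse"))
    expect_lte(partition_cost(pv), 2 * k * opt_r)
    expect_lte(opt_r, opt_d)
  }
})

test_that("assignment sampling is uniform over the worked label classes", {
  p <- ex3_pair()
  # B x3 and C x2 free: 3! * 2! = 12 equally likely assignments
  set.seed(2024)
  n_draw <- 6000
  keys <- character(n_draw)
  for (i in seq_len(n_draw)) {
    xi <- sample_assignment(p$g, p$h)
    validate_assignment(p$g, p$h, xi)
    keys[i] <- paste(xi, collapse = ",")
  }
  tab <- table(keys)
  expect_equal(length(tab), 12)
  expected <- n_draw / 12
  # within 3 standard deviations of the multinomial count
  sd3 <- 3 * sqrt(n_draw * (1 / 12) * (11 / 12))
  expect_true(all(abs(as.integer(tab) - expected) <= sd3))
})

test_that("partition-consistent sampling explores block matchings", {
  p1 <- ex1_pair()
  printed <- new_partition(p1$g, p1$h, c(3, 4, 6), c(1, 3, 6), "direct")
  set.seed(5)
  seen <- character(0)
  for (i in 1:50) {
    xi <- sample_assignment(p1$g, p1$h, printed)
    validate_assignment(p1$g, p1$h, xi)
    # the induced partition of a consistent assignment refines the blocks
    ind <- induced_partition(p1$g, p1$h, xi, "direct")
    expect_true(all(printed$source_breakpoints %in%
                    c(ind$source_breakpoints, -1) |
                    length(ind$source_breakpoints) >=
                    length(printed$source_breakpoints)))
    seen <- union(seen, paste(xi, collapse = ","))
  }
  # the two identical [D E] source blocks can map to two target slots
  expect_gte(length(seen), 2)

  # all-distinct labels admit exactly one assignment
  g <- genome(c("u","x","y","v"), c(1, 1, 1))
  h <- genome(c("u","y","x","v"), c(1, 1, 1))
  expect_equal(sample_assignment(g, h), c(1L, 3L, 2L, 4L))
})
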