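test_that("genome construction enforces the structural invariants", {
  g <- genome(c("I","B","B","A","C","A","A","F"), c(5, 1, 4, 3, 1, 3, 2))
  expect_s3_class(g, "genome")
  expect_equal(genome_size(g), 8)
  expect_equal(genome_size(genome("A")), 1)
  expect_error(genome(c("A", "B"), c(1, 2)), "length")
  expect_error(genome(c("A", "B"), -1), "non-negative")
})

test_that("reverse_genome matches the worked reversal and is an involution", {
  g <- fig1_genome()
  expect_equal(reverse_genome(g),
               genome(c("F","A","A","C","A","B","B","I"),
                      c(2, 3, 1, 3, 4, 1, 5)))
  expect_equal(reverse_genome(reverse_genome(g)), g)
  a <- genome("A")
  expect_equal(reverse_genome(a), a)
})

test_that("congruence holds for a genome, its reverse, and nothing weaker", {
  g <- fig1_genome()
  expect_true(congruent(g, g))
  expect_true(congruent(g, reverse_genome(g)))
  expect_false(congruent(genome(c("A","B"), 1), genome(c("A","B"), 2)))
})

test_that("combine and subgenome are inverse on the worked example", {
  g <- genome(c("B","A","B"), c(1, 3))
  h <- genome(c("C","D","A"), c(2, 2))
  k <- combine_genomes(g, h, 3)
  expect_equal(k, genome(c("B","A","B","C","D","A"), c(1, 3, 3, 2, 2)))
  expect_equal(subgenome(k, 1, 3), g)
  expect_equal(subgenome(k, 4, 6), h)
  expect_equal(subgenome(k, 1, genome_size(k)), k)
  expect_equal(combine_genomes(genome("A"), genome("B"), 0),
               genome(c("A","B"), 0))
  expect_error(subgenome(k, 4, 2), "indices")
  expect_error(combine_genomes(g, h, -1), "non-negative")
})

test_that("combine/subgenome round trip holds on random operands", {
  set.seed(101)
  for (i in 1:25) {
    na <- sample(1:5, 1); nb <- sample(1:5, 1)
    a <- genome(sample(letters[1:4], na, replace = TRUE),
                if (na > 1) sample(0:5, na - 1, replace = TRUE) else integer(0))
    b <- genome(sample(letters[1:4], nb, replace = TRUE),
                if (nb > 1) sample(0:5, nb - 1, replace = TRUE) else integer(0))
    gap <- sample(0:5, 1)
    k <- combine_genomes(a, b, gap)
    expect_equal(subgenome(k, 1, na), a)
    expect_equal(subgenome(k, na + 1, na + nb), b)
    expect_equal(k$intergenic[na], gap)
  }
})

test_that("balance compares label multisets and intergenic totals", {
  p <- ex1_pair()
  expect_true(is_balanced(p$g, p$h))
  expect_equal(intergenic_sum(p$g), 14)
  expect_equal(intergenic_sum(p$h), 14)
  g <- fig1_genome()
  expect_true(is_balanced(g, reverse_genome(g)))
  expect_false(is_balanced(genome(c("A","B"), 5), genome(c("A","B"), 4)))
  expect_false(is_balanced(genome(c("A","B"), 1), genome(c("A","A"), 1)))
})

test_that("max_occ reports the largest gene family", {
  p <- ex3_pair()
  expect_equal(max_occ(p$g), 3)
  expect_equal(max_occ(genome(c("A","B","C"), c(0, 0))), 1)
  expect_equal(max_occ(genome(c("A","A","A"), c(0, 0))), 3)
})

test_that("count_occurrences matches the worked counts and modes", {
  p <- ex3_pair()
  cb <- genome(c("C","B"), 1)
  expect_equal(count_occurrences(p$g, cb, "direct"), 1)
  expect_equal(count_occurrences(p$h, cb, "direct"), 0)
  expect_equal(count_occurrences(genome(c("A","B","A"), c(2, 2)),
                                 genome(c("B","A"), 2), "congruent"), 2)
})

test_that("count_occurrences agrees with a brute-force window scan", {
  brute <- function(g, x, mode) {
    n <- genome_size(g); m <- genome_size(x)
    if (m > n) return(0L)
    hits <- 0L
    for (i in 1:(n - m + 1)) {
      w <- subgenome(g, i, i + m - 1)
      ok <- if (mode == "direct") genomes_equal(w, x) else congruent(w, x)
      if (ok) hits <- hits + 1L
    }
    hits
  }
  set.seed(7)
  for (i in 1:40) {
    n <- sample(2:10, 1)
    g <- genome(sample(c("a", "b"), n, replace = TRUE),
                sample(0:2, n - 1, replace = TRUE))
    m <- sample(1:min(4, n), 1)
    s <- sample(1:(n - m + 1), 1)
    x <- subgenome(g, s, s + m - 1)
    for (mode in c("direct", "congruent")) {
      expect_identical(count_occurrences(g, x, mode), brute(g, x, mode))
    }
  }
})

test_that("congruent counting never undercounts relative to direct", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    g <- genome(sample(c("a", "b"), n, replace = TRUE),
                sample(0:2, n - 1, replace = TRUE))
    x <- subgenome(g, 1, sample(1:n, 1))
    expect_gte(count_occurrences(g, x, "congruent"),
               count_occurrences(g, x, "direct"))
  }
})

test_that("capping reproduces the worked extension and forces co-tails", {
  core <- genome(c("B","B","A","C","A","A"), c(1, 4, 3, 1, 3))
  expect_equal(cap_genome(core, "I", "F", 5, 2), fig1_genome())
  expect_equal(cap_genome(genome("A"), "I", "F", 0, 0),
               genome(c("I","A","F"), c(0, 0)))
  a <- cap_genome(genome(c("x","y"), 1), "s", "t", 2, 0)
  b <- cap_genome(genome(c("y","x"), 1), "s", "t", 1, 1)
  expect_true(is_cotailed(a, b))
})
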