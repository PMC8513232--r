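# Shared fixtures: the worked-example genomes, and generators for the
# small-instance families used by the property suites.

fx <- function(name) {
  read_genome(system.file("extdata", name, package = "igdist"))
}

fig1_genome <- function() genome(c("I","B","B","A","C","A","A","F"),
                                 c(5, 1, 4, 3, 1, 3, 2))
fig4_source <- function() genome(c("B","B","A","C","D","A"), c(5, 1, 4, 3, 1))

ex1_pair <- function() {
  list(g = genome(c("A","E","B","C","D","E","D","E"), c(1, 2, 2, 1, 3, 2, 3)),
       h = genome(c("C","D","E","A","E","B","D","E"), c(3, 3, 1, 1, 2, 1, 3)))
}
ex2_pair <- function() {
  list(g = genome(c("A","E","B","C","A","E","D","E","D"),
                  c(2, 1, 2, 2, 1, 3, 2, 3)),
       h = genome(c("C","D","E","A","A","E","B","D","E"),
                  c(4, 3, 1, 1, 2, 1, 1, 3)))
}
ex3_pair <- function() {
  list(g = genome(c("I","B","A","B","C","B","C","F"), c(1, 3, 2, 3, 1, 3, 2)),
       h = genome(c("I","B","C","A","B","B","C","F"), c(1, 3, 0, 2, 4, 3, 2)))
}

all_compositions <- function(total, parts) {
  if (parts == 0) return(if (total == 0) list(integer(0)) else list())
  out <- list()
  for (first in 0:total) {
    for (rest in all_compositions(total - first, parts - 1)) {
      out[[length(out) + 1]] <- c(first, rest)
    }
  }
  out
}

all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  seen <- character(0)
  for (i in seq_along(v)) {
    key <- v[i]
    if (key %in% seen) next
    seen <- c(seen, key)
    for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# Deterministic enumeration of balanced co-tailed pairs: for each core
# gene multiset, every ordered pair of arrangements is capped with a
# shared boundary pair, and every pair of intergenic compositions with
# equal total is attached.  `stride` thins the enumeration evenly.
enumerate_family <- function(cores, max_sum = 3, stride = 1) {
  pairs <- list()
  k <- 0
  for (core in cores) {
    n0 <- length(core)
    arrs <- all_perms(core)
    comps_by_sum <- lapply(0:max_sum, function(s) {
      all_compositions(s, n0 + 1)
    })
    for (a1 in arrs) for (a2 in arrs) {
      for (s in 0:max_sum) {
        for (ca in comps_by_sum[[s + 1]]) for (cb in comps_by_sum[[s + 1]]) {
          k <- k + 1
          if (k %% stride != 0) next
          pairs[[length(pairs) + 1]] <-
            list(g = genome(c("U", a1, "V"), ca),
                 h = genome(c("U", a2, "V"), cb))
        }
      }
    }
  }
  pairs
}

# random balanced co-tailed pair: unique caps, shuffled core, multinomial
# intergenic redistribution
random_cotailed_pair <- function(n_core = 4, labels = c("a", "b", "c"),
                                 max_gap = 3, cap_gap_max = 2) {
  g0 <- genome(sample(labels, n_core, replace = TRUE),
               if (n_core > 1) sample(0:max_gap, n_core - 1, replace = TRUE)
               else integer(0))
  h0 <- genome(sample(g0$genes),
               if (n_core > 1)
                 as.integer(rmultinom(1, intergenic_sum(g0),
                                      rep(1, n_core - 1))[, 1])
               else integer(0))
  sg <- sample(0:cap_gap_max, 1)
  eg <- sample(0:cap_gap_max, 1)
  list(g = cap_genome(g0, "CAP1", "CAP2", sg, eg),
       h = cap_genome(h0, "CAP1", "CAP2", sg, eg))
}

# random pair generated the way the simulation does: the target is the
# source after o random operations, so it is always reachable
random_operation_pair <- function(n_core = 8, m = 3, max_gap = 10, o = 3,
                                  model = "mixed") {
  g0 <- generate_source_genome(n_core, m, max_gap)
  h0 <- generate_target_genome(g0, model, o)
  gap1 <- sample(0:max_gap, 1)
  gap2 <- sample(0:max_gap, 1)
  list(g = cap_genome(g0, "CAP1", "CAP2", gap1, gap2),
       h = cap_genome(h0, "CAP1", "CAP2", gap1, gap2))
}

sorter_for <- function(model) {
  switch(model,
         transposition = sort_by_transpositions,
         reversal = sort_by_reversals,
         mixed = sort_by_reversals_and_transpositions)
}
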