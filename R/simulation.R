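# Simulated-genome experiment pipeline: random genome generation, random
# rearrangement application per model, capping, and the summary-statistic
# experiment comparing distance estimates with and without the partition.

#' Generate a random source genome
#'
#' Gene labels are drawn i.i.d. uniformly from an alphabet of `m`
#' symbols; intergenic sizes i.i.d. uniformly from the integers
#' `0..max_intergenic` (both ends inclusive).
#'
#' @param n Number of genes.
#' @param m Alphabet size.
#' @param max_intergenic Upper bound of the intergenic size range
#'   (default 100 nucleotides).
#' @return A `genome`.
#' @export
generate_source_genome <- function(n, m, max_intergenic = 100L) {
  stopifnot(n >= 1L, m >= 1L, max_intergenic >= 0L)
  labels <- paste0("g", seq_len(m))
  genome(sample(labels, n, replace = TRUE),
         if (n > 1L) sample.int(max_intergenic + 1L, n - 1L, replace = TRUE) - 1L
         else integer(0))
}

# one uniformly random valid operation of the given type
random_transposition <- function(g) {
  n <- length(g$genes)
  stopifnot(n >= 4L)
  idx <- sort(sample(2:n, 3L))
  transposition(idx[1L], idx[2L], idx[3L],
                sample.int(g$intergenic[idx[1L] - 1L] + 1L, 1L) - 1L,
                sample.int(g$intergenic[idx[2L] - 1L] + 1L, 1L) - 1L,
                sample.int(g$intergenic[idx[3L] - 1L] + 1L, 1L) - 1L)
}

random_reversal <- function(g) {
  n <- length(g$genes)
  stopifnot(n >= 4L)
  idx <- sort(sample(2:(n - 1L), 2L))
  reversal(idx[1L], idx[2L],
           sample.int(g$intergenic[idx[1L] - 1L] + 1L, 1L) - 1L,
           sample.int(g$intergenic[idx[2L]] + 1L, 1L) - 1L)
}

#' Apply random rearrangements to derive a target genome
#'
#' Applies `o` operations with uniformly drawn parameters: `o`
#' transpositions (`model = "transposition"`), `o` reversals
#' (`"reversal"`), or `floor(o/2)` reversals and `ceiling(o/2)`
#' transpositions in uniformly shuffled order (`"mixed"`).  Indices are
#' drawn uniformly over the valid tuples, then cut sizes uniformly over
#' their valid ranges given the current intergenic sizes.
#'
#' @param g Source `genome` (at least 4 genes when `o > 0`).
#' @param model `"transposition"`, `"reversal"` or `"mixed"`.
#' @param o Number of operations.
#' @return The rearranged `genome` (balanced with `g`).
#' @export
generate_target_genome <- function(g, model = c("transposition", "reversal", "mixed"),
                                   o) {
  model <- match.arg(model)
  o <- as.integer(o)
  stopifnot(o >= 0L)
  if (o == 0L) return(g)
  kinds <- switch(model,
                  transposition = rep("T", o),
                  reversal = rep("R", o),
                  mixed = sample(c(rep("R", o %/% 2L), rep("T", o - o %/% 2L))))
  for (k in kinds) {
    g <- if (k == "T") {
      apply_transposition(g, random_transposition(g))
    } else {
      apply_reversal(g, random_reversal(g))
    }
  }
  g
}

#' Experiment configuration
#'
#' @param model `"transposition"`, `"reversal"` or `"mixed"`.
#' @param m Alphabet size.
#' @param o Number of rearrangements applied per pair.
#' @param n_genes Genes per (uncapped) genome.
#' @param max_intergenic Intergenic size range upper bound.
#' @param n_pairs Genome pairs per set.
#' @param n_assignments Assignments sampled per pair and arm.
#' @param seed Integer seed for the whole experiment.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(model = c("transposition", "reversal", "mixed"),
                              m, o, n_genes = 100L, max_intergenic = 100L,
                              n_pairs = 100L, n_assignments = 100L,
                              seed = 1L) {
  model <- match.arg(model)
  cfg <- list(model = model, m = as.integer(m), o = as.integer(o),
              n_genes = as.integer(n_genes),
              max_intergenic = as.integer(max_intergenic),
              n_pairs = as.integer(n_pairs),
              n_assignments = as.integer(n_assignments),
              seed = as.integer(seed))
  stopifnot(cfg$m >= 1L, cfg$o >= 0L, cfg$n_genes >= 4L, cfg$n_pairs >= 1L,
            cfg$n_assignments >= 1L)
  structure(cfg, class = "experiment_config")
}

#' Build a database of capped genome pairs
#'
#' For each pair, a source genome is generated, the target derived by
#' random rearrangements, and both genomes are capped with the same
#' fresh boundary labels and the same cap gap sizes (drawn uniformly on
#' `0..max_intergenic` once per pair), so every pair is balanced and
#' co-tailed by construction.
#'
#' @param config An `experiment_config`.
#' @return List of `list(g =, h =)` capped genome pairs.
#' @export
build_database <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  lapply(seq_len(config$n_pairs), function(i) {
    g0 <- generate_source_genome(config$n_genes, config$m, config$max_intergenic)
    h0 <- generate_target_genome(g0, config$model, config$o)
    gap1 <- sample.int(config$max_intergenic + 1L, 1L) - 1L
    gap2 <- sample.int(config$max_intergenic + 1L, 1L) - 1L
    g <- cap_genome(g0, "CAP_START", "CAP_END", gap1, gap2)
    h <- cap_genome(h0, "CAP_START", "CAP_END", gap1, gap2)
    stopifnot(is_balanced(g, h), is_cotailed(g, h))
    list(g = g, h = h)
  })
}

#' Run a distance-estimation experiment
#'
#' For every generated pair, [estimate_distance()] is run twice: with
#' assignments consistent with the 2k-approximate partition for the
#' model, and with unconstrained per-label assignments.  The per-pair
#' minimum and average certified distances are aggregated into
#' min/avg/max summary statistics per arm.
#'
#' @param config An `experiment_config`.
#' @return A one-row data frame (`summary_row`) with the configuration
#'   and the `wp_*` (with partition) / `np_*` (no partition) statistics.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  pairs <- build_database(config)
  wp_min <- wp_avg <- np_min <- np_avg <- numeric(length(pairs))
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    wp <- estimate_distance(pr$g, pr$h, config$model,
                            n_assignments = config$n_assignments,
                            use_partition = TRUE)
    np <- estimate_distance(pr$g, pr$h, config$model,
                            n_assignments = config$n_assignments,
                            use_partition = FALSE)
    wp_min[i] <- wp$min_distance; wp_avg[i] <- wp$avg_distance
    np_min[i] <- np$min_distance; np_avg[i] <- np$avg_distance
  }
  data.frame(model = config$model, o = config$o, m = config$m,
             n_pairs = config$n_pairs, n_assignments = config$n_assignments,
             wp_min_min = min(wp_min), wp_min_avg = mean(wp_min),
             wp_min_max = max(wp_min),
             wp_avg_min = min(wp_avg), wp_avg_avg = mean(wp_avg),
             wp_avg_max = max(wp_avg),
             np_min_min = min(np_min), np_min_avg = mean(np_min),
             np_min_max = max(np_min),
             np_avg_min = min(np_avg), np_avg_avg = mean(np_avg),
             np_avg_max = max(np_avg))
}
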