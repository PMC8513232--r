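# Intergenic partitions: validity, assignment-induced minimal partitions,
# breakpoint classification, the 2k-approximation for the direct and
# reverse minimum common intergenic string partition problems, an exact
# brute-force oracle, and orthologous assignment sampling.

# ---- internal helpers -------------------------------------------------

# Sort key ordering genomes by (gene count, label sequence, intergenic
# sequence); integers are zero-padded so byte order equals numeric order.
genome_sort_key <- function(g) {
  paste(sprintf("%04d", length(g$genes)),
        paste(g$genes, collapse = "\x1f"),
        paste(sprintf("%012d", g$intergenic), collapse = "\x1f"),
        sep = "\x1f\x1f")
}

# Window (subgenome starting at s, m genes) of a genome, cheaply.
window_genome <- function(g, s, m) {
  if (m == 1L) {
    genome(g$genes[s], integer(0))
  } else {
    genome(g$genes[s:(s + m - 1L)], g$intergenic[s:(s + m - 2L)])
  }
}

# Identity key of a window without constructing a genome object.
window_key <- function(g, s, m) {
  paste(paste(g$genes[s:(s + m - 1L)], collapse = "\x1f"),
        if (m > 1L) paste(g$intergenic[s:(s + m - 2L)], collapse = "\x1f") else "",
        sep = "\x1f\x1f")
}

window_key_congruent <- function(g, s, m) {
  k1 <- window_key(g, s, m)
  k2 <- paste(paste(rev(g$genes[s:(s + m - 1L)]), collapse = "\x1f"),
              if (m > 1L) paste(rev(g$intergenic[s:(s + m - 2L)]), collapse = "\x1f") else "",
              sep = "\x1f\x1f")
  if (k1 <= k2) k1 else k2
}

# Canonical representative of a genome under congruence: the smaller of g
# and rev(g) in the (size, genes, intergenic) order.
canonical_congruent <- function(g) {
  gr <- reverse_genome(g)
  if (genome_sort_key(g) <= genome_sort_key(gr)) g else gr
}

normalize_block_list <- function(x) {
  if (inherits(x, "genome")) list(x) else x
}

# Split a genome at the given intergenic cut positions (sorted, unique,
# each in 1..n-1).  Returns a list of genome blocks; block b spans genes
# starts[b]..ends[b] of g.
split_blocks <- function(g, cuts) {
  n <- length(g$genes)
  cuts <- sort(unique(as.integer(cuts)))
  if (length(cuts) > 0L && (min(cuts) < 1L || max(cuts) > n - 1L)) {
    stop("breakpoint positions must lie in 1..n-1", call. = FALSE)
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  lapply(seq_along(starts), function(b) subgenome(g, starts[b], ends[b]))
}

block_ranges <- function(n, cuts) {
  cuts <- sort(unique(as.integer(cuts)))
  data.frame(start = c(1L, cuts + 1L), end = c(cuts, n))
}

# ---- weight and T_min --------------------------------------------------

#' Occurrence-count weight of a subgenome
#'
#' The weight of a genome `x` with respect to two block sequences is the
#' total number of occurrences of `x` within the blocks of `ss` minus the
#' total within the blocks of `ps`.  In `"congruent"` mode occurrences of
#' `x` in either orientation are counted.  A pair of block sequences forms
#' a valid (direct or reverse) intergenic partition exactly when every
#' subgenome has weight zero.
#'
#' @param ss,ps A `genome` or list of genomes (blocks).
#' @param x The query `genome`.
#' @param mode `"direct"` or `"congruent"`.
#' @return An integer (possibly negative).
#' @export
subgenome_weight <- function(ss, ps, x, mode = c("direct", "congruent")) {
  mode <- match.arg(mode)
  ss <- normalize_block_list(ss)
  ps <- normalize_block_list(ps)
  sum(vapply(ss, count_occurrences, integer(1), x = x, mode = mode)) -
    sum(vapply(ps, count_occurrences, integer(1), x = x, mode = mode))
}

# Tabulate keys of all windows of length m of genome g that do not span a
# cut position.  Returns a named count vector.
tabulate_windows <- function(g, cuts, m, congruent = FALSE) {
  n <- length(g$genes)
  if (m > n) return(integer(0))
  starts <- seq_len(n - m + 1L)
  if (length(cuts) > 0L && m > 1L) {
    ok <- vapply(starts, function(s) {
      !any(cuts >= s & cuts <= s + m - 2L)
    }, logical(1))
    starts <- starts[ok]
  }
  if (length(starts) == 0L) return(integer(0))
  keys <- vapply(starts, function(s) {
    if (congruent) window_key_congruent(g, s, m) else window_key(g, s, m)
  }, character(1))
  tab <- table(keys)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

# Merge two named count vectors by key subtraction (a - b).
subtract_counts <- function(a, b) {
  keys <- union(names(a), names(b))
  av <- ifelse(keys %in% names(a), a[keys], 0L)
  bv <- ifelse(keys %in% names(b), b[keys], 0L)
  out <- as.integer(av) - as.integer(bv)
  names(out) <- keys
  out
}

#' Containment-minimal non-zero-weight subgenomes (T_min)
#'
#' Enumerates every subgenome of the blocks of `ss` or `ps` whose weight
#' ([subgenome_weight()]) is non-zero, then keeps only those containing no
#' other such subgenome.  In `"congruent"` mode subgenomes are identified
#' up to congruence and containment allows either orientation.  Every
#' valid partition must cut at least one occurrence of each returned
#' entry, so the size of this set lower-bounds the attainable partition
#' cost (up to the factor 2k).
#'
#' Each entry carries the subgenome, its weight, and `break_offset`, the
#' intergenic position inside the subgenome designated as its associated
#' breakpoint (the first region, by convention).
#'
#' @param ss,ps A `genome` or list of genome blocks.
#' @param mode `"direct"` or `"congruent"`.
#' @return A list of entries `list(genome =, weight =, break_offset = 1)`,
#'   sorted by (size, gene labels, intergenic sizes).
#' @export
compute_tmin <- function(ss, ps, mode = c("direct", "congruent")) {
  mode <- match.arg(mode)
  ss <- normalize_block_list(ss)
  ps <- normalize_block_list(ps)
  congr <- mode == "congruent"
  if (length(ss) == 1L && length(ps) == 1L && !is_balanced(ss[[1L]], ps[[1L]])) {
    stop("compute_tmin requires balanced genomes", call. = FALSE)
  }

  max_m <- max(vapply(c(ss, ps), function(b) length(b$genes), integer(1)))
  nz <- list()      # key -> list(genome, weight)
  for (m in seq_len(max_m)) {
    cs <- integer(0)
    for (b in ss) {
      t1 <- tabulate_windows(b, integer(0), m, congr)
      cs <- if (length(cs)) subtract_counts(cs, -t1) else t1
    }
    # accumulate: cs currently holds S-side counts (subtract_counts with
    # negated b adds); now subtract P-side counts
    for (b in ps) {
      t1 <- tabulate_windows(b, integer(0), m, congr)
      cs <- subtract_counts(cs, t1)
    }
    w <- cs[cs != 0L]
    if (length(w) == 0L) next
    # recover a representative genome per key
    for (key in names(w)) {
      found <- FALSE
      for (b in c(ss, ps)) {
        nb <- length(b$genes)
        if (m > nb) next
        for (s in seq_len(nb - m + 1L)) {
          k <- if (congr) window_key_congruent(b, s, m) else window_key(b, s, m)
          if (k == key) {
            x <- window_genome(b, s, m)
            if (congr) x <- canonical_congruent(x)
            nz[[key]] <- list(genome = x, weight = as.integer(w[[key]]))
            found <- TRUE
            break
          }
        }
        if (found) break
      }
    }
  }
  if (length(nz) == 0L) return(list())

  # containment filter: drop X when a strictly smaller non-zero-weight
  # subgenome occurs inside it
  keys <- names(nz)
  keep <- logical(length(keys))
  for (idx in seq_along(keys)) {
    x <- nz[[idx]]$genome
    m <- length(x$genes)
    minimal <- TRUE
    for (mm in seq_len(max(m - 1L, 0L))) {
      for (s in seq_len(m - mm + 1L)) {
        k <- if (congr) window_key_congruent(x, s, mm) else window_key(x, s, mm)
        if (!is.null(nz[[k]])) {
          minimal <- FALSE
          break
        }
      }
      if (!minimal) break
    }
    keep[idx] <- minimal
  }
  ents <- nz[keep]
  ord <- order(vapply(ents, function(e) genome_sort_key(e$genome), character(1)),
               method = "radix")
  ents <- ents[ord]
  lapply(ents, function(e) {
    list(genome = e$genome, weight = e$weight, break_offset = 1L)
  })
}

# ---- partition object --------------------------------------------------

#' Construct an intergenic partition
#'
#' A partition records which intergenic regions of each genome are removed
#' (the breakpoints), splitting both genomes into blocks.  It is valid
#' when the source blocks can be reordered (direct mode) or reordered and
#' individually reversed (reverse mode) to give the target blocks; see
#' [validate_partition()].
#'
#' @param g,h Balanced genomes.
#' @param source_breakpoints Intergenic positions of `g` that are cut
#'   (1-based, each in `1..n-1`).
#' @param target_breakpoints Intergenic positions of `h` that are cut.
#' @param mode `"direct"` or `"reverse"`.
#' @return An object of class `igp_partition`.
#' @export
new_partition <- function(g, h, source_breakpoints, target_breakpoints,
                          mode = c("direct", "reverse")) {
  mode <- match.arg(mode)
  stopifnot(inherits(g, "genome"), inherits(h, "genome"))
  sb <- sort(unique(as.integer(source_breakpoints)))
  tb <- sort(unique(as.integer(target_breakpoints)))
  n <- length(g$genes)
  if (length(sb) > 0L && (min(sb) < 1L || max(sb) > n - 1L)) {
    stop("source breakpoints out of range", call. = FALSE)
  }
  if (length(tb) > 0L && (min(tb) < 1L || max(tb) > length(h$genes) - 1L)) {
    stop("target breakpoints out of range", call. = FALSE)
  }
  structure(list(g = g, h = h,
                 source_breakpoints = sb,
                 target_breakpoints = tb,
                 mode = mode,
                 cost = length(sb)),
            class = "igp_partition")
}

#' @export
print.igp_partition <- function(x, ...) {
  cat(sprintf("%s intergenic partition, cost %d\n",
              x$mode, x$cost))
  bs <- partition_blocks(x, "source")
  bp <- partition_blocks(x, "target")
  cat("  S:", paste(vapply(bs, format, character(1)), collapse = " "), "\n")
  cat("  P:", paste(vapply(bp, format, character(1)), collapse = " "), "\n")
  invisible(x)
}

#' Blocks of a partition
#'
#' @param p An `igp_partition`.
#' @param side `"source"` (blocks of the first genome) or `"target"`.
#' @return List of `genome` blocks in genome order.
#' @export
partition_blocks <- function(p, side = c("source", "target")) {
  side <- match.arg(side)
  if (side == "source") {
    split_blocks(p$g, p$source_breakpoints)
  } else {
    split_blocks(p$h, p$target_breakpoints)
  }
}

#' Cost of a partition
#'
#' The number of breakpoints, equal to the number of blocks minus one.
#'
#' @param p An `igp_partition`.
#' @return Integer cost.
#' @export
partition_cost <- function(p) {
  p$cost
}

# Bipartite block matching: returns data.frame(s_index, p_index, reversed)
# or NULL when no bijection exists.
match_blocks <- function(bs, bp, mode) {
  if (length(bs) != length(bp)) return(NULL)
  congr <- mode == "reverse"
  keyf <- function(b) {
    if (congr) genome_key_congruent(b) else genome_key(b)
  }
  ks <- vapply(bs, keyf, character(1))
  kp <- vapply(bp, keyf, character(1))
  if (!identical(sort(ks, method = "radix"), sort(kp, method = "radix"))) {
    return(NULL)
  }
  # assign within key classes in order of appearance
  pool <- split(seq_along(kp), kp)
  s_idx <- seq_along(ks)
  p_idx <- integer(length(ks))
  for (i in s_idx) {
    p_idx[i] <- pool[[ks[i]]][1L]
    pool[[ks[i]]] <- pool[[ks[i]]][-1L]
  }
  reversed <- vapply(seq_along(s_idx), function(i) {
    !genomes_equal(bs[[i]], bp[[p_idx[i]]])
  }, logical(1))
  data.frame(s_index = s_idx, p_index = p_idx, reversed = reversed)
}

#' Validate an intergenic partition
#'
#' Checks that the block sequences obtained by cutting the two genomes at
#' the partition's breakpoints can be matched bijectively, block for
#' block, by equality (direct mode) or congruence (reverse mode).  Two
#' independent criteria are evaluated: an explicit block matching, and
#' the weight-zero criterion (every subgenome occurs equally often within
#' the source blocks and within the target blocks).  The two criteria are
#' provably equivalent; the function stops with an error if they ever
#' disagree.
#'
#' @param p An `igp_partition`.
#' @param g,h Optionally, the genomes (default: those stored in `p`).
#' @return `TRUE` or `FALSE`.
#' @export
validate_partition <- function(p, g = p$g, h = p$h) {
  stopifnot(inherits(p, "igp_partition"))
  if (!is_balanced(g, h)) return(FALSE)
  bs <- split_blocks(g, p$source_breakpoints)
  bp <- split_blocks(h, p$target_breakpoints)
  by_matching <- !is.null(match_blocks(bs, bp, p$mode))

  # weight-zero criterion: the multiset of window keys over all blocks
  # must coincide on the two sides (equivalent to zero weight for every
  # subgenome of either genome)
  congr <- p$mode == "reverse"
  max_m <- max(length(g$genes), length(h$genes))
  by_weight <- TRUE
  for (m in seq_len(max_m)) {
    cs <- integer(0)
    for (b in bs) {
      t1 <- tabulate_windows(b, integer(0), m, congr)
      cs <- if (length(cs)) subtract_counts(cs, -t1) else t1
    }
    for (b in bp) {
      t1 <- tabulate_windows(b, integer(0), m, congr)
      cs <- subtract_counts(cs, t1)
    }
    if (any(cs != 0L)) {
      by_weight <- FALSE
      break
    }
  }
  if (by_matching != by_weight) {
    stop("internal error: block-matching and weight-zero validity checks disagree",
         call. = FALSE)
  }
  by_matching
}

# ---- the 2k-approximation ----------------------------------------------

# Find, among all subgenomes of the current blocks, the non-zero-weight
# one that is minimal under (size, genes, intergenic); smallest-size
# entries of T are always containment-minimal, so this is the least
# element of the current T_min.  Returns list(genome, weight) or NULL.
select_min_nonzero <- function(g, h, cuts_g, cuts_h, congr) {
  n <- max(length(g$genes), length(h$genes))
  if (n < 2L) return(NULL)
  for (m in 2:n) {
    ts <- tabulate_windows(g, cuts_g, m, congr)
    tp <- tabulate_windows(h, cuts_h, m, congr)
    w <- subtract_counts(ts, tp)
    w <- w[w != 0L]
    if (length(w) == 0L) next
    # choose the representative minimal under the sort-key order
    best <- NULL; best_key <- NULL
    for (key in names(w)) {
      x <- recover_window(g, h, cuts_g, cuts_h, m, key, congr)
      sk <- genome_sort_key(x)
      if (is.null(best_key) || sk < best_key) {
        best_key <- sk
        best <- list(genome = x, weight = as.integer(w[[key]]))
      }
    }
    return(best)
  }
  NULL
}

# Recover the genome for a window key from either genome (canonical
# orientation in congruent mode).
recover_window <- function(g, h, cuts_g, cuts_h, m, key, congr) {
  for (side in 1:2) {
    gg <- if (side == 1L) g else h
    cc <- if (side == 1L) cuts_g else cuts_h
    nb <- length(gg$genes)
    if (m > nb) next
    for (s in seq_len(nb - m + 1L)) {
      if (m > 1L && length(cc) > 0L && any(cc >= s & cc <= s + m - 2L)) next
      k <- if (congr) window_key_congruent(gg, s, m) else window_key(gg, s, m)
      if (k == key) {
        x <- window_genome(gg, s, m)
        if (congr) x <- canonical_congruent(x)
        return(x)
      }
    }
  }
  stop("internal error: window key not recoverable", call. = FALSE)
}

# Leftmost occurrence of x (or, in congruent mode, of rev(x)) in genome gg
# avoiding cut positions.  Returns list(start, reversed) or NULL.
leftmost_occurrence <- function(gg, cuts, x, congr) {
  n <- length(gg$genes)
  m <- length(x$genes)
  xr <- if (congr) reverse_genome(x) else NULL
  for (s in seq_len(n - m + 1L)) {
    if (m > 1L && length(cuts) > 0L && any(cuts >= s & cuts <= s + m - 2L)) next
    wg <- gg$genes[s:(s + m - 1L)]
    wi <- if (m > 1L) gg$intergenic[s:(s + m - 2L)] else integer(0)
    if (identical(wg, x$genes) && identical(as.integer(wi), as.integer(x$intergenic))) {
      return(list(start = s, reversed = FALSE))
    }
    if (congr && identical(wg, xr$genes) &&
        identical(as.integer(wi), as.integer(xr$intergenic))) {
      return(list(start = s, reversed = TRUE))
    }
  }
  NULL
}

# break(X) for an entry entering T_min mid-run: the offset, within an
# occurrence of X in the original genomes, of the chronologically first
# inserted breakpoint falling inside such an occurrence.
derive_break_offset <- function(x, g, h, log, congr) {
  m <- length(x$genes)
  xr <- if (congr) reverse_genome(x) else NULL
  for (entry in log) {
    gg <- if (entry$side == "S") g else h
    pos <- entry$pos
    n <- length(gg$genes)
    if (m > n) next
    for (s in seq_len(n - m + 1L)) {
      if (!(pos >= s && pos <= s + m - 2L)) next
      wg <- gg$genes[s:(s + m - 1L)]
      wi <- if (m > 1L) gg$intergenic[s:(s + m - 2L)] else integer(0)
      if (identical(wg, x$genes) &&
          identical(as.integer(wi), as.integer(x$intergenic))) {
        return(pos - s + 1L)
      }
      if (congr && identical(wg, xr$genes) &&
          identical(as.integer(wi), as.integer(xr$intergenic))) {
        return(m - (pos - s + 1L))
      }
    }
  }
  1L
}

algorithm1 <- function(g, h, mode) {
  congr <- mode == "reverse"
  if (!is_balanced(g, h)) {
    stop("partition requires balanced genomes", call. = FALSE)
  }
  n <- length(g$genes)
  cuts_g <- integer(0)
  cuts_h <- integer(0)
  log <- list()
  offsets <- new.env(parent = emptyenv())

  tmin0 <- compute_tmin(list(g), list(h),
                        mode = if (congr) "congruent" else "direct")
  for (e in tmin0) {
    kk <- if (congr) genome_key_congruent(e$genome) else genome_key(e$genome)
    assign(kk, 1L, envir = offsets)
  }

  max_iter <- 2L * (n - 1L) + 1L
  iter <- 0L
  repeat {
    sel <- select_min_nonzero(g, h, cuts_g, cuts_h, congr)
    if (is.null(sel)) break
    iter <- iter + 1L
    if (iter > max_iter) {
      stop("internal error: partition algorithm exceeded its iteration bound",
           call. = FALSE)
    }
    x <- sel$genome
    m <- length(x$genes)
    kk <- if (congr) genome_key_congruent(x) else genome_key(x)
    b <- if (exists(kk, envir = offsets, inherits = FALSE)) {
      get(kk, envir = offsets)
    } else {
      bo <- derive_break_offset(x, g, h, log, congr)
      assign(kk, bo, envir = offsets)
      bo
    }
    if (sel$weight > 0L) {
      occ <- leftmost_occurrence(g, cuts_g, x, congr)
      side <- "S"
    } else {
      occ <- leftmost_occurrence(h, cuts_h, x, congr)
      side <- "P"
    }
    if (is.null(occ)) {
      stop("internal error: no cuttable occurrence for a non-zero-weight subgenome",
           call. = FALSE)
    }
    pos <- if (occ$reversed) occ$start + (m - b) - 1L else occ$start + b - 1L
    if (side == "S") cuts_g <- sort(c(cuts_g, pos)) else cuts_h <- sort(c(cuts_h, pos))
    log[[length(log) + 1L]] <- list(side = side, pos = pos)
  }

  p <- new_partition(g, h, cuts_g, cuts_h,
                     mode = if (congr) "reverse" else "direct")
  attr(p, "n_tmin") <- length(tmin0)
  attr(p, "k") <- max_occ(g)
  p
}

#' Approximate minimum-cost direct intergenic partition (MCISP)
#'
#' Greedy breakpoint insertion: repeatedly pick the smallest subgenome
#' whose occurrence counts differ between the current source and target
#' blocks, and cut one surplus occurrence at that subgenome's designated
#' breakpoint.  The resulting partition is always valid and its cost is
#' at most `2k` times the size of the containment-minimal witness set
#' ([compute_tmin()]) — and hence at most `2k` times the optimum cost —
#' where `k` is the maximum gene multiplicity.
#'
#' Tie-breaks are deterministic: the candidate subgenome minimal under
#' (size, gene labels, intergenic sizes) is chosen, and the leftmost
#' occurrence on the surplus side is cut.
#'
#' @param g,h Balanced genomes.
#' @return A valid direct `igp_partition`; attributes `n_tmin` and `k`
#'   carry the witness-set size and the multiplicity bound.
#' @export
mcisp_partition <- function(g, h) {
  algorithm1(g, h, "direct")
}

#' Approximate minimum-cost reverse intergenic partition (RMCISP)
#'
#' The adaptation of [mcisp_partition()] in which subgenomes are counted
#' and matched up to congruence (equality after reversal), producing a
#' reverse intergenic partition with the same `2k` guarantee.
#'
#' @param g,h Balanced genomes.
#' @return A valid reverse `igp_partition`.
#' @export
rmcisp_partition <- function(g, h) {
  algorithm1(g, h, "reverse")
}

# ---- assignments -------------------------------------------------------

#' Validate an orthologous assignment
#'
#' An assignment maps each gene position of `g` to a gene position of `h`
#' carrying the same label, bijectively.
#'
#' @param g,h Balanced genomes.
#' @param xi Integer vector of length `n`; `xi[i]` is the position in `h`
#'   assigned to gene `i` of `g`.
#' @return `TRUE` invisibly; stops with a message if invalid.
#' @export
validate_assignment <- function(g, h, xi) {
  n <- length(g$genes)
  xi <- as.integer(xi)
  if (length(xi) != n || anyNA(xi)) {
    stop("assignment must be a complete integer vector of length n", call. = FALSE)
  }
  if (!identical(sort(xi), seq_len(n))) {
    stop("assignment must be a bijection over gene positions", call. = FALSE)
  }
  if (!all(g$genes == h$genes[xi])) {
    stop("assignment must preserve gene labels", call. = FALSE)
  }
  invisible(TRUE)
}

#' Minimal intergenic partition induced by an assignment
#'
#' Cuts the source genome after gene `i` exactly when the pair
#' `(i, i + 1)` does not extend a common block under the assignment: in
#' direct mode a non-cut requires the assigned genes to be consecutive in
#' the target, in the same order, with equal intergenic size between
#' them; in reverse mode a maximal run may instead be consistently
#' reverse-adjacent (each pair consecutive in the target in descending
#' order with matching sizes) — a change of direction forces a cut.  The
#' target breakpoints are the images of the cuts.  The result is the
#' unique minimal partition compatible with `xi`.
#'
#' @param g,h Balanced genomes.
#' @param xi An assignment (see [validate_assignment()]).
#' @param mode `"direct"` or `"reverse"`.
#' @return A valid `igp_partition`.
#' @export
induced_partition <- function(g, h, xi, mode = c("direct", "reverse")) {
  mode <- match.arg(mode)
  validate_assignment(g, h, xi)
  n <- length(g$genes)
  xi <- as.integer(xi)
  fwd <- function(i) xi[i + 1L] == xi[i] + 1L &&
    g$intergenic[i] == h$intergenic[xi[i]]
  bwd <- function(i) xi[i + 1L] == xi[i] - 1L &&
    g$intergenic[i] == h$intergenic[xi[i + 1L]]

  cuts <- integer(0)
  used_h <- integer(0)
  if (n >= 2L) {
    if (mode == "direct") {
      for (i in seq_len(n - 1L)) {
        if (fwd(i)) {
          used_h <- c(used_h, xi[i])
        } else {
          cuts <- c(cuts, i)
        }
      }
    } else {
      dir <- 0L
      for (i in seq_len(n - 1L)) {
        f <- fwd(i); b <- bwd(i)
        if (f && dir >= 0L) {
          dir <- 1L
          used_h <- c(used_h, xi[i])
        } else if (b && dir <= 0L) {
          dir <- -1L
          used_h <- c(used_h, xi[i + 1L])
        } else {
          cuts <- c(cuts, i)
          dir <- 0L
        }
      }
    }
  }
  cuts_h <- setdiff(seq_len(n - 1L), used_h)
  p <- new_partition(g, h, cuts, cuts_h, mode)
  if (length(cuts_h) != length(cuts)) {
    stop("internal error: induced partition is asymmetric", call. = FALSE)
  }
  p
}

#' Classify the breakpoints of an induced partition
#'
#' A source breakpoint after gene `i` is *hard* when the assigned genes
#' `xi(i)` and `xi(i + 1)` are consecutive (in order) in the target, so
#' only its intergenic size is wrong; otherwise it is *soft*.  A hard
#' breakpoint is *overcharged* when its region is larger than the
#' assigned target region and *undercharged* when smaller.
#'
#' @param g,h Balanced genomes.
#' @param xi The assignment that induced `p`.
#' @param p The induced `igp_partition`.
#' @return A data frame with columns `position`, `kind`
#'   (`"soft"`/`"hard"`) and `charge` (`"overcharged"`, `"undercharged"`
#'   or `"none"`).
#' @export
classify_breakpoints <- function(g, h, xi, p) {
  validate_assignment(g, h, xi)
  bps <- p$source_breakpoints
  if (length(bps) == 0L) {
    return(data.frame(position = integer(0), kind = character(0),
                      charge = character(0)))
  }
  kind <- character(length(bps))
  charge <- character(length(bps))
  for (t in seq_along(bps)) {
    i <- bps[t]
    hard <- xi[i + 1L] == xi[i] + 1L
    kind[t] <- if (hard) "hard" else "soft"
    if (hard) {
      si <- g$intergenic[i]
      ti <- h$intergenic[xi[i]]
      charge[t] <- if (si > ti) "overcharged" else if (si < ti) "undercharged" else "none"
    } else {
      charge[t] <- "none"
    }
  }
  data.frame(position = bps, kind = kind, charge = charge)
}

# ---- exact oracle ------------------------------------------------------

#' Exact minimum-cost intergenic partition by exhaustive search
#'
#' Enumerates source breakpoint subsets in increasing cardinality and, for
#' each, searches for a target cut set of the same size whose blocks match
#' the source blocks by equality (direct) or congruence (reverse).  The
#' first feasible pair is optimal.  Intended as a small-instance oracle.
#'
#' @param g,h Balanced genomes.
#' @param mode `"direct"` or `"reverse"`.
#' @param max_size Guard on the genome size (default 12).
#' @return A minimum-cost `igp_partition`.
#' @export
brute_force_min_partition <- function(g, h, mode = c("direct", "reverse"),
                                      max_size = 12L) {
  mode <- match.arg(mode)
  if (!is_balanced(g, h)) {
    stop("brute_force_min_partition requires balanced genomes", call. = FALSE)
  }
  n <- length(g$genes)
  if (n > max_size) {
    stop(sprintf("instance too large for exhaustive search (n = %d > %d)",
                 n, max_size), call. = FALSE)
  }
  congr <- mode == "reverse"
  keyf <- function(b) if (congr) genome_key_congruent(b) else genome_key(b)

  # precompute block keys for every gene range
  keymat <- matrix(NA_character_, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      keymat[i, j] <- keyf(subgenome(g, i, j))
    }
  }
  keymat_h <- matrix(NA_character_, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      keymat_h[i, j] <- keyf(subgenome(h, i, j))
    }
  }
  block_sig <- function(keymat, cuts) {
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, n)
    paste(sort(keymat[cbind(starts, ends)], method = "radix"),
          collapse = "\x01")
  }
  positions <- seq_len(n - 1L)
  for (cost in 0:(n - 1L)) {
    subsets_g <- if (cost == 0L) list(integer(0)) else
      utils::combn(positions, cost, simplify = FALSE)
    sigs_h <- new.env(parent = emptyenv())
    subsets_h <- if (cost == 0L) list(integer(0)) else
      utils::combn(positions, cost, simplify = FALSE)
    for (ch in subsets_h) {
      sig <- block_sig(keymat_h, ch)
      if (!exists(sig, envir = sigs_h, inherits = FALSE)) {
        assign(sig, ch, envir = sigs_h)
      }
    }
    for (cg in subsets_g) {
      sig <- block_sig(keymat, cg)
      if (exists(sig, envir = sigs_h, inherits = FALSE)) {
        ch <- get(sig, envir = sigs_h)
        return(new_partition(g, h, cg, ch, mode))
      }
    }
  }
  stop("internal error: no partition found (genomes unbalanced?)", call. = FALSE)
}

# ---- assignment sampling -----------------------------------------------

#' Sample an orthologous assignment
#'
#' Without a partition, draws an independent uniform random bijection per
#' gene label (singletons map to their unique counterpart).  With a
#' partition, first draws a uniform random matching between source and
#' target blocks within each equality class (congruence class in reverse
#' mode), then maps genes positionally within each matched pair —
#' reversed for a reversed block match.
#'
#' Randomness is drawn from R's global generator; seed with [set.seed()]
#' for reproducibility.
#'
#' @param g,h Balanced genomes.
#' @param p Optionally, a valid `igp_partition` between `g` and `h`.
#' @return An assignment vector `xi` (see [validate_assignment()]).
#' @export
sample_assignment <- function(g, h, p = NULL) {
  n <- length(g$genes)
  if (is.null(p)) {
    xi <- integer(n)
    for (lab in unique(g$genes)) {
      pos_g <- which(g$genes == lab)
      pos_h <- which(h$genes == lab)
      xi[pos_g] <- if (length(pos_h) == 1L) pos_h else sample(pos_h)
    }
    validate_assignment(g, h, xi)
    return(xi)
  }
  stopifnot(inherits(p, "igp_partition"))
  bs <- partition_blocks(p, "source")
  bp <- partition_blocks(p, "target")
  congr <- p$mode == "reverse"
  keyf <- function(b) if (congr) genome_key_congruent(b) else genome_key(b)
  ks <- vapply(bs, keyf, character(1))
  kp <- vapply(bp, keyf, character(1))
  rng_s <- block_ranges(n, p$source_breakpoints)
  rng_p <- block_ranges(length(h$genes), p$target_breakpoints)
  if (!identical(sort(ks, method = "radix"), sort(kp, method = "radix"))) {
    stop("partition is not valid: blocks cannot be matched", call. = FALSE)
  }
  xi <- integer(n)
  for (key in unique(ks)) {
    is_ <- which(ks == key)
    ip_ <- which(kp == key)
    perm <- if (length(ip_) == 1L) ip_ else sample(ip_)
    for (t in seq_along(is_)) {
      sb <- is_[t]; pb <- perm[t]
      gs <- rng_s$start[sb]:rng_s$end[sb]
      hs <- rng_p$start[pb]:rng_p$end[pb]
      if (genomes_equal(bs[[sb]], bp[[pb]])) {
        xi[gs] <- hs
      } else {
        xi[gs] <- rev(hs)
      }
    }
  }
  validate_assignment(g, h, xi)
  xi
}
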