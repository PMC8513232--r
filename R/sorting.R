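# Constructive sorting between balanced co-tailed genomes under a given
# orthologous assignment, meeting partition-based upper bounds; plus
# partition lower bounds, an exact BFS distance oracle, and the
# assignment-sampling distance estimation pipeline.

# region of h assigned to source intergenic region i (the region after
# the assigned image of gene i); Inf when undefined (image is last gene)
xi_region <- function(h, xi, i) {
  pos <- xi[i]
  if (pos >= length(h$genes)) Inf else h$intergenic[pos]
}

update_xi <- function(xi, n, op) {
  perm <- if (inherits(op, "transposition")) {
    transposition_perm(n, op$i, op$j, op$k)
  } else {
    reversal_perm(n, op$i, op$j)
  }
  xi[perm]
}

check_sorting_preconditions <- function(g, h, xi) {
  if (!is_balanced(g, h)) stop("sorting requires balanced genomes", call. = FALSE)
  if (!is_cotailed(g, h)) stop("sorting requires co-tailed genomes", call. = FALSE)
  validate_assignment(g, h, xi)
  n <- length(g$genes)
  if (xi[1L] != 1L || xi[n] != n) {
    stop("sorting requires an assignment fixing the co-tail genes", call. = FALSE)
  }
  invisible(TRUE)
}

# Order-preserving per-label assignment: the k-th occurrence of each
# label in g is matched to the k-th occurrence in h.  Often induces far
# fewer breakpoints than an arbitrary assignment; since any valid
# assignment yields a sequence transforming g into h, the sorters may
# freely substitute it when it is cheaper.
order_preserving_assignment <- function(g, h) {
  xi <- integer(length(g$genes))
  for (lab in unique(g$genes)) {
    xi[which(g$genes == lab)] <- which(h$genes == lab)
  }
  xi
}

new_sorting_result <- function(operations, model, partition_cost, bound) {
  structure(list(operations = operations, model = model,
                 partition_cost = partition_cost, bound = bound),
            class = "sorting_result")
}

#' @export
print.sorting_result <- function(x, ...) {
  cat(sprintf("sorting result: %d %s operation(s), partition cost %d, bound %d\n",
              length(x$operations), x$model, x$partition_cost, x$bound))
  for (op in x$operations) cat(" ", format_op(op), "\n")
  invisible(x)
}

# ---- transposition sorter ---------------------------------------------

#' Transposition removing a soft breakpoint
#'
#' Given an assignment whose induced minimal direct partition has a soft
#' breakpoint after gene `i` with at least as many nucleotides as its
#' assigned target region, constructs one intergenic transposition whose
#' application strictly decreases the induced partition cost.  The moved
#' segment closes the breakpoint by making gene `i` adjacent to the gene
#' whose image follows the image of gene `i`, with the new region set to
#' the assigned size; cut sizes for the remaining junctions are chosen to
#' avoid creating overcharged breakpoints where possible.
#'
#' @param g,h Balanced co-tailed genomes.
#' @param xi An assignment fixing the co-tail genes.
#' @return A `transposition`.
#' @export
remove_soft_breakpoint <- function(g, h, xi) {
  check_sorting_preconditions(g, h, xi)
  p <- induced_partition(g, h, xi, "direct")
  cls <- classify_breakpoints(g, h, xi, p)
  bps <- p$source_breakpoints
  soft <- cls$position[cls$kind == "soft"]
  qual <- soft[vapply(soft, function(i) {
    g$intergenic[i] >= xi_region(h, xi, i)
  }, logical(1))]
  if (length(qual) == 0L) {
    stop("no soft breakpoint with sufficient nucleotides exists", call. = FALSE)
  }
  i <- qual[1L]
  tgt <- as.integer(xi_region(h, xi, i))
  j <- which(xi == xi[i] + 1L)
  stopifnot(length(j) == 1L, j != i + 1L)
  n <- length(g$genes)

  # Build the transposition for a given auxiliary breakpoint k and free
  # cut value; the junction (S_i, S_j) is always set to the assigned
  # size, so the breakpoint after gene i is removed.
  construct <- function(k, free) {
    if (j > i && k < i) {
      # tau(k+1, i+1, j): junctions (S_k, S_{i+1}) = x + y',
      # (S_{j-1}, S_{k+1}) = z + x', (S_i, S_j) = y + z'
      transposition(k + 1L, i + 1L, j,
                    x = free, y = tgt, z = g$intergenic[j - 1L])
    } else if (j > i) {
      # tau(i+1, j, k+1): junctions (S_i, S_j) = x + y',
      # (S_k, S_{i+1}) = z + x', (S_{j-1}, S_{k+1}) = y + z'
      transposition(i + 1L, j, k + 1L,
                    x = tgt, y = g$intergenic[j - 1L], z = free)
    } else {
      # tau(j, k+1, i+1): junctions (S_{j-1}, S_{k+1}) = x + y',
      # (S_i, S_j) = z + x', (S_k, S_{i+1}) = y + z'
      transposition(j, k + 1L, i + 1L,
                    x = g$intergenic[j - 1L], y = free, z = tgt)
    }
  }

  ks <- if (j > i) bps[bps < i | bps >= j] else bps[bps >= j & bps < i]
  if (length(ks) == 0L) {
    stop("internal error: no auxiliary breakpoint for the soft-breakpoint move",
         call. = FALSE)
  }

  # Candidate free-cut values per auxiliary breakpoint: both extremes
  # plus the value matching the assigned size of the junction that the
  # free cut feeds (the overcharge-avoidance choice).
  e_rest <- g$intergenic[i] - tgt
  before <- length(bps)
  best <- NULL
  best_score <- NULL
  for (k in ks) {
    cap <- g$intergenic[k]
    t1 <- xi_region(h, xi, k)
    crit <- if (is.finite(t1)) max(0L, min(cap, as.integer(t1) - e_rest)) else 0L
    for (free in unique(c(0L, crit, cap))) {
      op <- tryCatch(construct(k, free), error = function(e) NULL)
      if (is.null(op)) next
      g2 <- tryCatch(apply_transposition(g, op), error = function(e) NULL)
      if (is.null(g2)) next
      xi2 <- update_xi(xi, n, op)
      p2 <- induced_partition(g2, h, xi2, "direct")
      if (length(p2$source_breakpoints) >= before) next
      cls2 <- classify_breakpoints(g2, h, xi2, p2)
      score <- c(sum(cls2$charge == "overcharged"),
                 length(p2$source_breakpoints))
      if (is.null(best_score) ||
          score[1L] < best_score[1L] ||
          (score[1L] == best_score[1L] && score[2L] < best_score[2L])) {
        best <- op
        best_score <- score
      }
    }
  }
  if (is.null(best)) {
    stop("internal error: no breakpoint-removing transposition found",
         call. = FALSE)
  }
  best
}

#' Sort one genome into another by intergenic transpositions
#'
#' Transforms `g` into `h` with at most `cost + 1` intergenic
#' transpositions, where `cost` is the cost of the minimal direct
#' partition induced by the assignment `xi`.  Three cases are applied in
#' order until no breakpoint remains: (1) two or more overcharged hard
#' breakpoints are discharged by a two-transposition nucleotide
#' redistribution; (2) a soft breakpoint with sufficient nucleotides is
#' removed by one transposition ([remove_soft_breakpoint()]); (3) a
#' single remaining overcharged breakpoint is discharged against an
#' undercharged or soft breakpoint.  The result is verified by
#' application and the bound is asserted.
#'
#' @param g,h Balanced co-tailed genomes of size at least 4 (unless
#'   `g` equals `h`).
#' @param xi An assignment fixing the co-tail genes.
#' @return A `sorting_result` with model `"transposition"`.
#' @export
sort_by_transpositions <- function(g, h, xi) {
  check_sorting_preconditions(g, h, xi)
  n <- length(g$genes)
  cost0 <- partition_cost(induced_partition(g, h, xi, "direct"))
  opa <- order_preserving_assignment(g, h)
  xi_used <- if (partition_cost(induced_partition(g, h, opa, "direct")) <
                 cost0) opa else xi
  ops <- list()
  gcur <- g
  xic <- as.integer(xi_used)
  max_iter <- 2L * max(cost0, 1L) + 4L
  iter <- 0L

  repeat {
    p <- induced_partition(gcur, h, xic, "direct")
    bps <- p$source_breakpoints
    if (length(bps) == 0L) break
    if (n < 4L) {
      stop("unsortable under model: no transposition applicable (n < 4)",
           call. = FALSE)
    }
    iter <- iter + 1L
    if (iter > max_iter) {
      stop("internal error: transposition sorter exceeded its iteration bound",
           call. = FALSE)
    }
    cls <- classify_breakpoints(gcur, h, xic, p)
    over <- cls$position[cls$charge == "overcharged"]
    soft <- cls$position[cls$kind == "soft"]
    under <- cls$position[cls$charge == "undercharged"]
    qual <- soft[vapply(soft, function(i) {
      gcur$intergenic[i] >= xi_region(h, xic, i)
    }, logical(1))]

    redistribute <- function(r1, r2, r3, t1, t2, t3) {
      regs <- c(r1, r2, r3)
      tg <- c(t1, t2, t3)
      o <- order(regs)
      two <- redistribute_three(gcur, regs[o][1L], regs[o][2L], regs[o][3L],
                                tg[o])
      for (op in two) {
        ops[[length(ops) + 1L]] <<- op
        gcur <<- apply_transposition(gcur, op)
      }
    }

    if (length(over) >= 2L) {
      i1 <- over[1L]; j1 <- over[2L]
      k1 <- setdiff(bps, c(i1, j1))[1L]
      t_i <- as.integer(xi_region(h, xic, i1))
      t_j <- as.integer(xi_region(h, xic, j1))
      rest <- gcur$intergenic[i1] + gcur$intergenic[j1] + gcur$intergenic[k1] -
        t_i - t_j
      redistribute(i1, j1, k1, t_i, t_j, rest)
    } else if (length(qual) >= 1L) {
      op <- remove_soft_breakpoint(gcur, h, xic)
      before <- length(bps)
      ops[[length(ops) + 1L]] <- op
      gcur <- apply_transposition(gcur, op)
      xic <- update_xi(xic, n, op)
      after <- partition_cost(induced_partition(gcur, h, xic, "direct"))
      if (after >= before) {
        stop("internal error: soft-breakpoint move failed to reduce the cost",
             call. = FALSE)
      }
    } else if (length(over) == 1L) {
      j1 <- over[1L]
      t_j <- as.integer(xi_region(h, xic, j1))
      if (length(under) >= 1L) {
        k1 <- under[1L]
        t_k <- as.integer(xi_region(h, xic, k1))
        others <- setdiff(bps, c(j1, k1))
        if (length(others) >= 1L) {
          l1 <- others[1L]
          rest <- gcur$intergenic[j1] + gcur$intergenic[k1] +
            gcur$intergenic[l1] - t_j - t_k
          redistribute(j1, k1, l1, t_j, t_k, rest)
        } else {
          r3 <- setdiff(seq_len(n - 1L), c(j1, k1))[1L]
          redistribute(j1, k1, r3, t_j, t_k, gcur$intergenic[r3])
        }
      } else {
        s1 <- soft[1L]
        excess <- gcur$intergenic[j1] - t_j
        others <- setdiff(bps, c(j1, s1))
        if (length(others) >= 1L) {
          t1 <- others[1L]
          redistribute(j1, s1, t1, t_j, gcur$intergenic[s1] + excess,
                       gcur$intergenic[t1])
        } else {
          r3 <- setdiff(seq_len(n - 1L), c(j1, s1))[1L]
          redistribute(j1, s1, r3, t_j, gcur$intergenic[s1] + excess,
                       gcur$intergenic[r3])
        }
      }
    } else {
      stop("internal error: no applicable transposition case (conservation violated?)",
           call. = FALSE)
    }
  }

  if (!genomes_equal(gcur, h)) {
    stop("internal error: transposition sorter did not reach the target genome",
         call. = FALSE)
  }
  if (length(ops) > cost0 + 1L) {
    stop(sprintf(
      "internal error: transposition sorter used %d operations, above the bound %d",
      length(ops), cost0 + 1L), call. = FALSE)
  }
  new_sorting_result(ops, "transposition", cost0, cost0 + 1L)
}

# ---- reversal and mixed sorters ---------------------------------------

# Shared block-placement engine.  Places the target's blocks left to
# right; each placement uses one reversal (block present in opposite
# orientation), two reversals (same orientation; reversal model), or one
# transposition (same orientation; mixed model).  Junction sizes are set
# exactly via the cut sizes, with extra "gather" reversals pooling free
# nucleotides at the prefix boundary when the regions cut by a placement
# cannot supply the junction target.
place_blocks_engine <- function(g, h, xi, model, prefer = c("flip", "sweep"),
                                gather_pick = c("max", "near")) {
  prefer <- match.arg(prefer)
  gather_pick <- match.arg(gather_pick)
  p <- induced_partition(g, h, xi, "reverse")
  cost0 <- partition_cost(p)
  n <- length(g$genes)
  if (cost0 == 0L) {
    if (!genomes_equal(g, h)) {
      stop("internal error: zero-cost reverse partition but genomes differ",
           call. = FALSE)
    }
    return(list(ops = list(), cost = cost0))
  }
  if (n < 4L) {
    stop("unsortable under model: no reversal applicable (n < 4)", call. = FALSE)
  }
  rs <- block_ranges(n, p$source_breakpoints)
  rh <- block_ranges(n, p$target_breakpoints)
  B <- nrow(rs)
  stopifnot(nrow(rh) == B)

  # natural block correspondence from the assignment
  phi <- integer(B)        # phi[t] = source block placed at target slot t
  needsign <- integer(B)   # +1 canonical orientation, -1 reversed
  for (b in seq_len(B)) {
    s0 <- rs$start[b]; e0 <- rs$end[b]
    h_lo <- min(xi[s0], xi[e0])
    t <- which(rh$start == h_lo)
    if (length(t) != 1L || rh$end[t] != max(xi[s0], xi[e0])) {
      stop("internal error: induced blocks do not map onto target blocks",
           call. = FALSE)
    }
    phi[t] <- b
    needsign[t] <- if (e0 > s0 && xi[s0] > xi[e0]) -1L else 1L
  }
  if (phi[1L] != 1L || needsign[1L] != 1L || phi[B] != B || needsign[B] != 1L) {
    stop("internal error: co-tail blocks are not anchored", call. = FALSE)
  }
  blk <- lapply(seq_len(B), function(b) subgenome(g, rs$start[b], rs$end[b]))
  palin <- vapply(blk, function(b) genomes_equal(b, reverse_genome(b)), logical(1))
  lens <- rs$end - rs$start + 1L
  jt <- h$intergenic[sort(p$target_breakpoints)]

  ops <- list()
  gcur <- g
  ord <- seq_len(B)
  sgn <- rep(1L, B)

  push <- function(op) {
    ops[[length(ops) + 1L]] <<- op
    gcur <<- if (inherits(op, "transposition")) {
      apply_transposition(gcur, op)
    } else {
      apply_reversal(gcur, op)
    }
  }
  slot_end <- function(s) sum(lens[ord[seq_len(s)]])
  flip_slots <- function(a, b) {
    ord[a:b] <<- rev(ord[a:b])
    sgn[a:b] <<- -rev(sgn[a:b])
  }

  # A pair of reversals over the same span redistributes nucleotides
  # between regions a and b (b >= a + 2) and restores every gene and
  # every other region, so the span may freely cut through blocks.
  transfer_pair <- function(a, b, new_a) {
    stopifnot(b >= a + 2L, a >= 1L, b <= n - 1L)
    va <- gcur$intergenic[a]; vb <- gcur$intergenic[b]
    stopifnot(new_a >= 0L, new_a <= va + vb)
    push(reversal(a + 1L, b, va, vb))
    push(reversal(a + 1L, b, new_a, 0L))
  }
  # Redistribution between adjacent regions a, a + 1 through a borrowed
  # (and exactly restored) intermediate region; 4 reversals.  When no
  # intermediate exists (only on tiny genomes) the nucleotides are
  # immovable and sorting under the reversal model is impossible.
  transfer_adjacent <- function(a, new_a) {
    va <- gcur$intergenic[a]; vb <- gcur$intergenic[a + 1L]
    stopifnot(new_a >= 0L, new_a <= va + vb)
    if (new_a == va) return(invisible())
    delta <- new_a - va
    if (a - 2L >= 1L) {
      m <- a - 2L
      vm <- gcur$intergenic[m]
      if (delta > 0L) {
        transfer_pair(m, a + 1L, vm + delta)
        transfer_pair(m, a, vm)
      } else {
        transfer_pair(m, a, vm - delta)
        transfer_pair(m, a + 1L, vm)
      }
    } else if (a + 3L <= n - 1L) {
      m <- a + 3L
      if (delta > 0L) {
        transfer_pair(a + 1L, m, vb - delta)
        transfer_pair(a, m, new_a)
      } else {
        transfer_pair(a, m, new_a)
        transfer_pair(a + 1L, m, vb - delta)
      }
    } else if (a >= 2L && a + 2L <= n - 1L) {
      # three-gene rotation: couples the two adjacent regions through the
      # flanking regions (restored exactly) while returning the gene
      # order to its original state; 4 reversals.  Two symmetric variants
      # cover every conserving target split between them.
      vA <- gcur$intergenic[a - 1L]
      vd <- gcur$intergenic[a + 2L]
      if (new_a <= vA + vb) {
        push(reversal(a, a + 1L, vA, vb))
        push(reversal(a, a + 2L, vA + vb - new_a, 0L))
        y3 <- min(va, vA)
        push(reversal(a, a + 1L, vA - y3, y3))
        push(reversal(a + 1L, a + 2L, 0L, new_a))
      } else if (new_a >= vb - vd) {
        tt <- vA + va + vb - new_a
        s1 <- min(va + vd, tt)
        s2 <- tt - s1
        x1 <- min(va, s1); y1 <- s1 - x1
        x2 <- min(vA, s2); y2 <- s2 - x2
        x3 <- min(vb, new_a); y3 <- new_a - x3
        x4 <- min(s2, vA); y4 <- vA - x4
        push(reversal(a + 1L, a + 2L, x1, y1))
        push(reversal(a, a + 2L, x2, y2))
        push(reversal(a + 1L, a + 2L, x3, y3))
        push(reversal(a, a + 1L, x4, y4))
      } else {
        stop("unsortable under model: nucleotides immovable across a junction",
             call. = FALSE)
      }
    } else {
      stop("unsortable under model: nucleotides immovable across a junction",
           call. = FALSE)
    }
    if (gcur$intergenic[a] != new_a) {
      stop("internal error: adjacent transfer failed verification", call. = FALSE)
    }
    invisible()
  }

  for (t in 2:B) {
    bid <- phi[t]
    want <- needsign[t]
    target <- jt[t - 1L]
    guard <- 0L
    repeat {
      guard <- guard + 1L
      if (guard > 4L * B + 16L) {
        stop("internal error: block placement did not converge", call. = FALSE)
      }
      idx <- which(ord == bid)
      e <- slot_end(t - 1L)
      r <- slot_end(idx)
      q <- r - lens[bid] + 1L
      ok_sign <- sgn[idx] == want || palin[bid]

      if (idx == t && ok_sign && gcur$intergenic[e] == target) break

      if (t == B) {
        # all earlier junctions exact: conservation forces the last one
        stop("internal error: last junction not satisfied by conservation",
             call. = FALSE)
      }

      # boundary regions strictly inside the unplaced area
      fb <- if (t <= B - 1L) vapply(t:(B - 1L), slot_end, integer(1)) else integer(0)
      gather <- function(min_pos = e + 2L) {
        cand <- fb[fb >= min_pos & gcur$intergenic[fb] > 0L]
        if (length(cand) == 0L) return(FALSE)
        m <- if (gather_pick == "max") cand[which.max(gcur$intergenic[cand])]
             else cand[1L]
        sl <- which(vapply(seq_len(B), slot_end, integer(1)) == m)
        push(reversal(e + 1L, m, gcur$intergenic[e], gcur$intergenic[m]))
        flip_slots(t, sl)
        TRUE
      }
      # When no boundary can be gathered by a reversal, set region e to
      # the junction target directly: in the mixed model a two-
      # transposition redistribution over free boundary regions does it
      # without moving any block; under reversals alone the nucleotides
      # are pulled across the adjacent boundary via borrowed regions.
      fix_pool <- function() {
        if (model != "mixed") {
          # set region e to the junction target against a free boundary;
          # a reversal pair couples regions two or more apart directly,
          # adjacent boundaries go through borrowed intermediates
          cand <- fb[fb >= e + 2L]
          if (length(cand) > 0L) {
            m <- cand[which.max(gcur$intergenic[cand])]
            if (gcur$intergenic[e] + gcur$intergenic[m] >= target) {
              transfer_pair(e, m, target)
              return(invisible())
            }
          }
          if (!((e + 1L) %in% fb)) {
            stop("internal error: junction fix would disturb a block interior",
                 call. = FALSE)
          }
          transfer_adjacent(e, target)
          return(invisible())
        }
        rounds <- 0L
        repeat {
          ve <- gcur$intergenic[e]
          if (ve == target) return(invisible())
          rounds <- rounds + 1L
          if (rounds > B + 2L) {
            stop("internal error: junction redistribution did not converge",
                 call. = FALSE)
          }
          if (ve > target) {
            m1 <- fb[1L]
            r3 <- setdiff(seq_len(n - 1L), c(e, m1))[1L]
            regs <- sort(c(e, m1, r3))
            tg <- integer(3)
            tg[regs == e] <- target
            tg[regs == m1] <- gcur$intergenic[m1] + (ve - target)
            tg[regs == r3] <- gcur$intergenic[r3]
            for (op in redistribute_three(gcur, regs[1L], regs[2L], regs[3L], tg)) {
              push(op)
            }
          } else {
            rich <- fb[order(gcur$intergenic[fb], decreasing = TRUE)]
            m1 <- rich[1L]
            m2_free <- length(rich) >= 2L
            m2 <- if (m2_free) rich[2L] else
              setdiff(seq_len(n - 1L), c(e, m1))[1L]
            pool <- ve + gcur$intergenic[m1] +
              if (m2_free) gcur$intergenic[m2] else 0L
            tset <- min(target, pool)
            regs <- sort(c(e, m1, m2))
            tg <- integer(3)
            tg[regs == e] <- tset
            tg[regs == m1] <- pool - tset
            tg[regs == m2] <- if (m2_free) 0L else gcur$intergenic[m2]
            for (op in redistribute_three(gcur, regs[1L], regs[2L], regs[3L], tg)) {
              push(op)
            }
          }
        }
      }

      if (idx == t && ok_sign) {
        # in place but the junction is wrong: pull nucleotides in from a
        # later boundary, or swap across this block when it is the only
        # unplaced boundary left
        if (gather()) next
        fix_pool()
        next
      }

      # placement cascade: a one-reversal flip when it lands the needed
      # orientation and its two cut regions cover the junction target; an
      # orientation-preserving move (two reversals, or one transposition
      # in the mixed model) whose pool also includes the boundary before
      # the block; then pooling repairs
      can_flip <- sgn[idx] != want || palin[bid]
      can_fwd <- idx > t && lens[bid] >= 2L && (sgn[idx] == want || palin[bid])
      pool1 <- gcur$intergenic[e] + gcur$intergenic[r]
      pool_fwd <- pool1 + gcur$intergenic[q - 1L]
      pool_tr <- gcur$intergenic[e] + gcur$intergenic[q - 1L]

      do_flip <- function() {
        x <- min(gcur$intergenic[e], target)
        push(reversal(e + 1L, r, x, target - x))
        flip_slots(t, idx)
      }
      do_fwd <- function() {
        if (model == "mixed" && pool_tr >= target) {
          # one transposition slides the block to the front
          x <- min(gcur$intergenic[e], target)
          yp <- target - x
          y <- gcur$intergenic[q - 1L] - yp
          push(transposition(e + 1L, q, r + 1L, x, y, gcur$intergenic[r]))
          ord <<- c(ord[seq_len(t - 1L)], ord[idx],
                    ord[t:(idx - 1L)],
                    if (idx < B) ord[(idx + 1L):B] else integer(0))
          sgn <<- c(sgn[seq_len(t - 1L)], sgn[idx],
                    sgn[t:(idx - 1L)],
                    if (idx < B) sgn[(idx + 1L):B] else integer(0))
        } else {
          # sweep the free pool forward, then flip into place; the second
          # reversal sets the junction and parks the leftover at the new
          # prefix boundary
          push(reversal(e + 1L, r, gcur$intergenic[e], gcur$intergenic[r]))
          flip_slots(t, idx)
          m <- slot_end(t)
          x2 <- min(gcur$intergenic[e], target)
          push(reversal(e + 1L, m, x2, target - x2))
          flip_slots(t, t)
        }
      }
      fwd_pool_ok <- can_fwd && pool_fwd >= target
      flip_pool_ok <- can_flip && pool1 >= target
      if (prefer == "sweep" && fwd_pool_ok) {
        do_fwd()
        next
      }
      if (flip_pool_ok) {
        do_flip()
        next
      }
      if (fwd_pool_ok) {
        do_fwd()
        next
      }
      if (gather()) next
      fix_pool()
      next
    }
  }

  if (!genomes_equal(gcur, h)) {
    stop("internal error: block placement did not reach the target genome",
         call. = FALSE)
  }
  list(ops = ops, cost = cost0)
}

#' Sort one genome into another by intergenic reversals
#'
#' Transforms `g` into `h` with at most `2 * cost` intergenic reversals,
#' where `cost` is the cost of the minimal reverse partition induced by
#' `xi`.  Target blocks are placed left to right: a block present in the
#' opposite orientation costs one reversal, one in the same orientation
#' two; junction sizes are set exactly through the cut sizes.  The result
#' is verified by application and the bound asserted.
#'
#' @param g,h Balanced co-tailed genomes.
#' @param xi An assignment fixing the co-tail genes.
#' @return A `sorting_result` with model `"reversal"`.
#' @export
sort_by_reversals <- function(g, h, xi) {
  check_sorting_preconditions(g, h, xi)
  res <- best_placement(g, h, xi, "reversal")
  bound <- 2L * res$cost
  if (length(res$ops) > bound) {
    alt <- bfs_path(g, h, "reversal")
    if (!is.null(alt) && length(alt) <= bound &&
        genomes_equal(apply_ops(g, alt), h)) {
      res$ops <- alt
    } else {
      stop(sprintf(
        "internal error: reversal sorter used %d operations, above the bound %d",
        length(res$ops), bound), call. = FALSE)
    }
  }
  new_sorting_result(res$ops, "reversal", res$cost, bound)
}

# Exact shortest operation sequence by breadth-first search with parent
# tracking; NULL when the instance exceeds the guards or the target is
# unreachable.  Fallback for tiny instances where the greedy placement
# exceeds its bound.
bfs_path <- function(g, h, model, max_size = 6L, max_sum = 8L) {
  n <- length(g$genes)
  if (n > max_size || intergenic_sum(g) > max_sum) return(NULL)
  target <- genome_key(h)
  if (genome_key(g) == target) return(list())
  seen <- new.env(parent = emptyenv())
  assign(genome_key(g), TRUE, envir = seen)
  frontier <- list(list(g = g, ops = list()))
  for (depth in seq_len(2L * n)) {
    nxt <- list()
    for (st in frontier) {
      cur <- st$g
      cand <- list()
      if (model %in% c("transposition", "mixed") && n >= 4L) {
        for (i in 2:(n - 2L)) for (j in (i + 1L):(n - 1L)) for (k in (j + 1L):n) {
          for (x in 0:cur$intergenic[i - 1L]) for (y in 0:cur$intergenic[j - 1L])
            for (z in 0:cur$intergenic[k - 1L]) {
              cand[[length(cand) + 1L]] <- transposition(i, j, k, x, y, z)
            }
        }
      }
      if (model %in% c("reversal", "mixed") && n >= 4L) {
        for (i in 2:(n - 2L)) for (j in (i + 1L):(n - 1L)) {
          for (x in 0:cur$intergenic[i - 1L]) for (y in 0:cur$intergenic[j]) {
            cand[[length(cand) + 1L]] <- reversal(i, j, x, y)
          }
        }
      }
      for (op in cand) {
        nb <- if (inherits(op, "transposition")) {
          apply_transposition(cur, op)
        } else {
          apply_reversal(cur, op)
        }
        key <- genome_key(nb)
        if (key == target) return(c(st$ops, list(op)))
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- list(g = nb, ops = c(st$ops, list(op)))
        }
      }
    }
    if (length(nxt) == 0L) return(NULL)
    frontier <- nxt
  }
  NULL
}

# Run the placement engine under both greedy preferences (one-reversal
# flips first, or pool-sweeping moves first) and keep the shorter
# certified sequence.
best_placement <- function(g, h, xi, model) {
  cost0 <- partition_cost(induced_partition(g, h, xi, "reverse"))
  opa <- order_preserving_assignment(g, h)
  xis <- list(xi)
  if (partition_cost(induced_partition(g, h, opa, "reverse")) < cost0 &&
      !identical(as.integer(opa), as.integer(xi))) {
    xis <- c(list(opa), xis)
  }
  goal <- if (model == "mixed") ceiling(1.5 * cost0) else 2L * cost0
  best <- NULL
  err <- NULL
  for (xi_used in xis) {
    for (prefer in c("flip", "sweep")) {
      for (gather_pick in c("max", "near")) {
        res <- tryCatch(
          place_blocks_engine(g, h, xi_used, model, prefer, gather_pick),
          error = function(e) e)
        if (inherits(res, "error")) {
          err <- res
          next
        }
        if (is.null(best) || length(res$ops) < length(best$ops)) best <- res
        if (length(best$ops) <= goal) {
          best$cost <- cost0
          return(best)
        }
      }
    }
  }
  if (is.null(best)) stop(err)
  best$cost <- cost0
  best
}

#' Sort by intergenic reversals and transpositions
#'
#' Transforms `g` into `h` with at most `ceiling(1.5 * cost)` operations
#' (reversals or transpositions), where `cost` is the induced reverse
#' partition cost.  Blocks in the needed orientation are slid into place
#' by a single transposition, reversed blocks by a single reversal.  The
#' reversal-only construction is also computed and the shorter sequence
#' returned, so the mixed result is never worse than the reversal-only
#' one.  The result is verified and the bound asserted.
#'
#' @param g,h Balanced co-tailed genomes.
#' @param xi An assignment fixing the co-tail genes.
#' @return A `sorting_result` with model `"mixed"`.
#' @export
sort_by_reversals_and_transpositions <- function(g, h, xi) {
  check_sorting_preconditions(g, h, xi)
  res <- best_placement(g, h, xi, "mixed")
  alt <- tryCatch(best_placement(g, h, xi, "reversal"), error = function(e) NULL)
  ops <- if (!is.null(alt) && length(alt$ops) < length(res$ops)) alt$ops else res$ops
  bound <- as.integer(ceiling(1.5 * res$cost))
  if (length(ops) > bound) {
    fb <- bfs_path(g, h, "mixed")
    if (!is.null(fb) && length(fb) <= bound &&
        genomes_equal(apply_ops(g, fb), h)) {
      ops <- fb
    } else {
      stop(sprintf(
        "internal error: mixed sorter used %d operations, above the bound %d",
        length(ops), bound), call. = FALSE)
    }
  }
  new_sorting_result(ops, "mixed", res$cost, bound)
}

# ---- bounds and oracle --------------------------------------------------

#' Partition-based lower bound on the rearrangement distance
#'
#' A transposition can remove at most three breakpoints of a minimal
#' partition, a reversal at most two, so the minimum partition cost
#' divided by 3 (transpositions, mixed) or 2 (reversals) bounds the
#' distance from below.  Uses the exhaustive partition oracle, so only
#' small instances are accepted.
#'
#' @param g,h Balanced genomes.
#' @param model `"transposition"`, `"reversal"` or `"mixed"`.
#' @param max_size Guard forwarded to [brute_force_min_partition()].
#' @return A non-negative integer.
#' @export
partition_lower_bound <- function(g, h,
                                  model = c("transposition", "reversal", "mixed"),
                                  max_size = 12L) {
  model <- match.arg(model)
  mode <- if (model == "transposition") "direct" else "reverse"
  pstar <- partition_cost(brute_force_min_partition(g, h, mode, max_size))
  if (model == "reversal") as.integer(ceiling(pstar / 2)) else
    as.integer(ceiling(pstar / 3))
}

# enumerate all genomes reachable from g in one operation under a model
neighbor_genomes <- function(g, model) {
  n <- length(g$genes)
  out <- list()
  if (model %in% c("transposition", "mixed") && n >= 4L) {
    for (i in 2:(n - 2L)) for (j in (i + 1L):(n - 1L)) for (k in (j + 1L):n) {
      for (x in 0:g$intergenic[i - 1L]) for (y in 0:g$intergenic[j - 1L])
        for (z in 0:g$intergenic[k - 1L]) {
          out[[length(out) + 1L]] <-
            apply_transposition(g, transposition(i, j, k, x, y, z))
        }
    }
  }
  if (model %in% c("reversal", "mixed") && n >= 4L) {
    for (i in 2:(n - 2L)) for (j in (i + 1L):(n - 1L)) {
      for (x in 0:g$intergenic[i - 1L]) for (y in 0:g$intergenic[j]) {
        out[[length(out) + 1L]] <-
          apply_reversal(g, reversal(i, j, x, y))
      }
    }
  }
  out
}

#' Exact rearrangement distance by breadth-first search
#'
#' Explores all genomes reachable from `g` under the model's operations
#' in breadth-first order until `h` is found.  Exponential; guarded to
#' tiny instances.
#'
#' @param g,h Balanced co-tailed genomes.
#' @param model `"transposition"`, `"reversal"` or `"mixed"`.
#' @param max_size,max_sum Guards on genome size and intergenic sum.
#' @return The exact distance (non-negative integer).
#' @export
bfs_exact_distance <- function(g, h,
                               model = c("transposition", "reversal", "mixed"),
                               max_size = 6L, max_sum = 6L) {
  model <- match.arg(model)
  if (!is_balanced(g, h)) stop("BFS distance requires balanced genomes", call. = FALSE)
  n <- length(g$genes)
  if (n > max_size || intergenic_sum(g) > max_sum) {
    stop(sprintf(
      "instance too large for BFS (n = %d > %d or intergenic sum %d > %d)",
      n, max_size, intergenic_sum(g), max_sum), call. = FALSE)
  }
  target <- genome_key(h)
  if (genome_key(g) == target) return(0L)
  seen <- new.env(parent = emptyenv())
  assign(genome_key(g), TRUE, envir = seen)
  frontier <- list(g)
  depth <- 0L
  while (length(frontier) > 0L) {
    depth <- depth + 1L
    nxt <- list()
    for (cur in frontier) {
      for (nb in neighbor_genomes(cur, model)) {
        key <- genome_key(nb)
        if (key == target) return(depth)
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- nb
        }
      }
    }
    frontier <- nxt
  }
  stop("target genome unreachable under the model", call. = FALSE)
}

# ---- distance estimation -----------------------------------------------

sorter_for_model <- function(model) {
  switch(model,
         transposition = sort_by_transpositions,
         reversal = sort_by_reversals,
         mixed = sort_by_reversals_and_transpositions)
}

#' Estimate a rearrangement distance over sampled assignments
#'
#' Samples orthologous assignments (uniformly; optionally consistent with
#' the 2k-approximate partition for the model), sorts `g` into `h` under
#' each, and reports the minimum and mean certified sequence lengths.
#' Every reported length is certified: the operation sequence is
#' re-applied and must reproduce `h` exactly.
#'
#' @param g,h Balanced co-tailed genomes.
#' @param model `"transposition"`, `"reversal"` or `"mixed"`.
#' @param n_assignments Number of assignments to sample.
#' @param use_partition Sample assignments consistent with the
#'   approximate partition (`TRUE`) or unconstrained per-label
#'   assignments (`FALSE`).
#' @return A `distance_estimate` with fields `min_distance`,
#'   `avg_distance`, `n_assignments`, `used_partition`, `model`.
#' @export
estimate_distance <- function(g, h,
                              model = c("transposition", "reversal", "mixed"),
                              n_assignments = 100L, use_partition = TRUE) {
  model <- match.arg(model)
  sorter <- sorter_for_model(model)
  p <- if (use_partition) {
    if (model == "transposition") mcisp_partition(g, h) else rmcisp_partition(g, h)
  } else NULL
  lens <- integer(n_assignments)
  for (a in seq_len(n_assignments)) {
    xi <- sample_assignment(g, h, p)
    res <- sorter(g, h, xi)
    if (!genomes_equal(apply_ops(g, res$operations), h)) {
      stop("internal error: sorting sequence failed certification", call. = FALSE)
    }
    lens[a] <- length(res$operations)
  }
  structure(list(min_distance = min(lens),
                 avg_distance = mean(lens),
                 n_assignments = n_assignments,
                 used_partition = use_partition,
                 model = model),
            class = "distance_estimate")
}

#' @export
print.distance_estimate <- function(x, ...) {
  cat(sprintf(
    "distance estimate (%s, %s partition): min %d, avg %.2f over %d assignments\n",
    x$model, if (x$used_partition) "with" else "without",
    x$min_distance, x$avg_distance, x$n_assignments))
  invisible(x)
}
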