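#' Construct a genome
#'
#' A genome is modelled as an ordered sequence of gene labels interleaved
#' with the sizes (in nucleotides) of the intergenic regions separating
#' consecutive genes.  A genome of size `n` therefore carries `n` gene
#' labels and `n - 1` non-negative integer intergenic sizes.  Labels are
#' opaque tokens compared by equality only; multi-character labels are
#' allowed.
#'
#' @param genes Character vector of gene labels (length at least 1).
#' @param intergenic Integer vector of non-negative intergenic region
#'   sizes, one fewer than `genes`.
#' @return An object of class `genome`.
#' @examples
#' g <- genome(c("I", "B", "B", "A", "C", "A", "A", "F"),
#'             c(5, 1, 4, 3, 1, 3, 2))
#' genome_size(g)
#' @export
genome <- function(genes, intergenic = integer(0)) {
  genes <- as.character(genes)
  if (length(genes) < 1L) {
    stop("a genome must contain at least one gene", call. = FALSE)
  }
  if (length(intergenic) == 0L) {
    intergenic <- integer(0)
  } else {
    intergenic <- as.integer(intergenic)
  }
  if (length(intergenic) != length(genes) - 1L) {
    stop(sprintf(
      "intergenic sequence must have length %d (one fewer than genes), got %d",
      length(genes) - 1L, length(intergenic)
    ), call. = FALSE)
  }
  if (anyNA(genes) || anyNA(intergenic)) {
    stop("genome components must not contain NA", call. = FALSE)
  }
  if (any(intergenic < 0L)) {
    stop("intergenic region sizes must be non-negative", call. = FALSE)
  }
  structure(list(genes = genes, intergenic = intergenic), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("genome of size", length(x$genes), "\n")
  cat("  genes:     ", paste(x$genes, collapse = " "), "\n")
  cat("  intergenic:", paste(x$intergenic, collapse = " "), "\n")
  invisible(x)
}

#' @export
format.genome <- function(x, ...) {
  sprintf("([%s],[%s])",
          paste(x$genes, collapse = " "),
          paste(x$intergenic, collapse = " "))
}

#' Number of genes in a genome
#' @param g A `genome`.
#' @return Integer size `n`.
#' @export
genome_size <- function(g) {
  stopifnot(inherits(g, "genome"))
  length(g$genes)
}

#' Total intergenic content of a genome
#' @param g A `genome`.
#' @return Sum of all intergenic region sizes (nucleotides).
#' @export
intergenic_sum <- function(g) {
  stopifnot(inherits(g, "genome"))
  sum(g$intergenic)
}

#' Reverse a genome
#'
#' Reverses both the gene sequence and the intergenic size sequence, so the
#' genome is read right to left.  An involution: reversing twice yields the
#' original genome.
#'
#' @param g A `genome`.
#' @return The reversed `genome`.
#' @export
reverse_genome <- function(g) {
  stopifnot(inherits(g, "genome"))
  genome(rev(g$genes), rev(g$intergenic))
}

#' Test two genomes for equality
#'
#' Equality compares gene labels and intergenic sizes exactly.
#'
#' @param g,h Genomes.
#' @return `TRUE` or `FALSE`.
#' @export
genomes_equal <- function(g, h) {
  identical(g$genes, h$genes) &&
    identical(as.integer(g$intergenic), as.integer(h$intergenic))
}

#' Test two genomes for congruence
#'
#' Two genomes are congruent when they are equal or one equals the reverse
#' of the other (both labels and intergenic sizes).
#'
#' @param g,h Genomes.
#' @return `TRUE` or `FALSE`.
#' @export
congruent <- function(g, h) {
  genomes_equal(g, h) || genomes_equal(g, reverse_genome(h))
}

#' Extract a subgenome
#'
#' The subgenome between genes `i` and `j` (1-based, inclusive) carries the
#' `j - i` intergenic regions lying strictly between those genes; the
#' flanking regions are dropped.
#'
#' @param g A `genome`.
#' @param i,j 1-based gene indices with `i <= j`.
#' @return A `genome` of size `j - i + 1`.
#' @export
subgenome <- function(g, i, j) {
  stopifnot(inherits(g, "genome"))
  n <- length(g$genes)
  if (!(i >= 1L && j <= n && i <= j)) {
    stop(sprintf("invalid subgenome indices (i = %d, j = %d, n = %d)", i, j, n),
         call. = FALSE)
  }
  if (i == j) {
    genome(g$genes[i], integer(0))
  } else {
    genome(g$genes[i:j], g$intergenic[i:(j - 1L)])
  }
}

#' Combine two genomes
#'
#' Concatenates `g` and `h` into a single genome, inserting a new
#' intergenic region of size `gap` at the junction.  The operands are
#' recoverable as subgenomes of the result.
#'
#' @param g,h Genomes.
#' @param gap Non-negative size of the inserted intergenic region.
#' @return The combined `genome`.
#' @export
combine_genomes <- function(g, h, gap = 0L) {
  stopifnot(inherits(g, "genome"), inherits(h, "genome"))
  gap <- as.integer(gap)
  if (is.na(gap) || gap < 0L) {
    stop("gap must be a non-negative integer", call. = FALSE)
  }
  genome(c(g$genes, h$genes), c(g$intergenic, gap, h$intergenic))
}

#' Test whether two genomes are balanced
#'
#' Balanced genomes have the same multiset of gene labels and equal total
#' intergenic size.  Balance is the precondition for conservative-event
#' rearrangement distances: transpositions and reversals can transform one
#' genome into the other only if they are balanced.
#'
#' @param g,h Genomes.
#' @return `TRUE` or `FALSE`.
#' @export
is_balanced <- function(g, h) {
  stopifnot(inherits(g, "genome"), inherits(h, "genome"))
  if (length(g$genes) != length(h$genes)) return(FALSE)
  tg <- table(g$genes)
  th <- table(h$genes)
  if (length(tg) != length(th)) return(FALSE)
  if (!all(sort(names(tg)) == sort(names(th)))) return(FALSE)
  if (!all(tg[sort(names(tg))] == th[sort(names(tg))])) return(FALSE)
  sum(g$intergenic) == sum(h$intergenic)
}

#' Test whether two genomes are co-tailed
#'
#' Co-tailed genomes share their first and their last gene label, as
#' guaranteed by capping both genomes of a pair with the same artificial
#' gene pair.
#'
#' @param g,h Genomes.
#' @return `TRUE` or `FALSE`.
#' @export
is_cotailed <- function(g, h) {
  g$genes[1L] == h$genes[1L] &&
    g$genes[length(g$genes)] == h$genes[length(h$genes)]
}

#' Maximum gene multiplicity
#'
#' The largest number of copies of any single gene label, the parameter
#' `k` in the 2k approximation guarantee of the partition algorithms.
#'
#' @param g A `genome`.
#' @return A positive integer.
#' @export
max_occ <- function(g) {
  stopifnot(inherits(g, "genome"))
  max(table(g$genes))
}

#' Count occurrences of a subgenome
#'
#' Counts the windows `(i, j)` of `g` whose subgenome is equal (mode
#' `"direct"`) or congruent (mode `"congruent"`) to `x`.  A window equal to
#' a palindromic `x` (one with `x = rev(x)`) is counted once.  Occurrences
#' compare gene labels and the intergenic sizes between them; the flanking
#' regions of the window are ignored.
#'
#' @param g A `genome` to scan.
#' @param x The query `genome`.
#' @param mode `"direct"` or `"congruent"`.
#' @return Non-negative integer count.
#' @export
count_occurrences <- function(g, x, mode = c("direct", "congruent")) {
  mode <- match.arg(mode)
  stopifnot(inherits(g, "genome"), inherits(x, "genome"))
  n <- length(g$genes)
  m <- length(x$genes)
  if (m > n) return(0L)
  xr <- if (mode == "congruent") reverse_genome(x) else NULL
  cnt <- 0L
  for (i in seq_len(n - m + 1L)) {
    w_genes <- g$genes[i:(i + m - 1L)]
    w_inter <- if (m > 1L) g$intergenic[i:(i + m - 2L)] else integer(0)
    hit <- identical(w_genes, x$genes) &&
      identical(as.integer(w_inter), as.integer(x$intergenic))
    if (!hit && mode == "congruent") {
      hit <- identical(w_genes, xr$genes) &&
        identical(as.integer(w_inter), as.integer(xr$intergenic))
    }
    if (hit) cnt <- cnt + 1L
  }
  cnt
}

#' Cap (extend) a genome with artificial boundary genes
#'
#' Adds an artificial first and last gene so that any two genomes capped
#' with the same pair of labels become co-tailed.  The caller is
#' responsible for choosing cap labels not present in the genome.
#'
#' @param g A `genome`.
#' @param start_label,end_label Labels of the artificial boundary genes.
#' @param start_gap,end_gap Non-negative intergenic sizes inserted between
#'   the caps and the original genome.
#' @return A `genome` of size `n + 2`.
#' @export
cap_genome <- function(g, start_label, end_label, start_gap = 0L, end_gap = 0L) {
  stopifnot(inherits(g, "genome"))
  start_gap <- as.integer(start_gap)
  end_gap <- as.integer(end_gap)
  if (start_gap < 0L || end_gap < 0L) {
    stop("cap gaps must be non-negative", call. = FALSE)
  }
  genome(c(start_label, g$genes, end_label),
         c(start_gap, g$intergenic, end_gap))
}

# Canonical single-string key of a genome; used for hashing BFS states and
# deduplicating subgenome sets.  "\x1f" cannot occur in labels read from the
# whitespace-separated file format.
genome_key <- function(g) {
  paste(paste(g$genes, collapse = "\x1f"),
        paste(g$intergenic, collapse = "\x1f"),
        sep = "\x1f\x1f")
}

# Canonical key under congruence: the lexicographically smaller of the keys
# of g and rev(g).
genome_key_congruent <- function(g) {
  k1 <- genome_key(g)
  k2 <- genome_key(reverse_genome(g))
  if (k1 <= k2) k1 else k2
}
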