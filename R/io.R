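# Plain-text genome files and serialization helpers.
#
# A genome file holds two whitespace-separated lines: gene labels, then
# the intergenic sizes (one fewer).  Lines starting with '#' are ignored.

#' Read a genome from a two-line text file
#'
#' Line 1 carries whitespace-separated gene labels (arbitrary
#' non-whitespace tokens), line 2 the non-negative integer intergenic
#' sizes, one fewer than the labels.  Comment lines starting with `#`
#' and blank lines are skipped.
#'
#' @param path Path to the file.
#' @return A `genome`.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("genome file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 1L) {
    stop(sprintf("%s: empty genome file", path), call. = FALSE)
  }
  genes <- strsplit(lines[1L], "[[:space:]]+")[[1L]]
  inter <- if (length(lines) >= 2L) {
    toks <- strsplit(lines[2L], "[[:space:]]+")[[1L]]
    vals <- suppressWarnings(as.integer(toks))
    if (anyNA(vals)) {
      stop(sprintf("%s: line 2: intergenic sizes must be integers", path),
           call. = FALSE)
    }
    vals
  } else integer(0)
  if (length(inter) != length(genes) - 1L) {
    stop(sprintf(
      "%s: line 2: expected %d intergenic sizes (one fewer than genes), got %d",
      path, length(genes) - 1L, length(inter)), call. = FALSE)
  }
  if (any(inter < 0L)) {
    stop(sprintf("%s: line 2: intergenic sizes must be non-negative", path),
         call. = FALSE)
  }
  genome(genes, inter)
}

#' Write a genome to its canonical two-line text form
#'
#' Single-space separated, newline-terminated; the round trip through
#' [read_genome()] is the identity.
#'
#' @param g A `genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(g, path) {
  stopifnot(inherits(g, "genome"))
  writeLines(c(paste(g$genes, collapse = " "),
               paste(g$intergenic, collapse = " ")), path)
  invisible(path)
}

#' One-line summary of a partition
#'
#' Tab-separated `cost`, `k` (maximum gene multiplicity) and, when known,
#' the size of the containment-minimal witness set.
#'
#' @param p An `igp_partition`.
#' @return A character scalar.
#' @export
format_partition_summary <- function(p) {
  k <- attr(p, "k")
  nt <- attr(p, "n_tmin")
  paste(c(sprintf("cost\t%d", p$cost),
          if (!is.null(k)) sprintf("k\t%d", k),
          if (!is.null(nt)) sprintf("n_tmin\t%d", nt)),
        collapse = "\n")
}
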