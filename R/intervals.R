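#' Construct a table of genomic intervals
#'
#' Intervals are the universal currency of the package: peaks, motif hits and
#' candidate CRMs are all tibbles with at least `chrom`, `start`, `end`.
#' Coordinates are 0-based half-open (BED-native): `start` is the first base
#' of the feature, `end` is one past the last, and the length is
#' `end - start`.
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start Integer vector, 0-based inclusive start positions.
#' @param end Integer vector, 0-based exclusive end positions.
#' @param name Optional feature labels (`NA` allowed).
#' @param score Optional numeric annotation (`NA` allowed).
#' @param strand Strand, one of `"+"`, `"-"`, `"."`; `"."` means unstranded.
#'
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, validated so that `0 <= start < end` on every row.
#' @examples
#' genomic_interval("chr1", 100, 200)
#' @export
genomic_interval <- function(chrom, start, end, name = NA_character_,
                             score = NA_real_, strand = ".") {
  x <- tibble::tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = as.character(name),
    score = as.numeric(score),
    strand = as.character(strand)
  )
  validate_intervals(x)
  x
}

#' Validate an interval table
#'
#' Checks the interval invariants: non-empty chromosome names, integer
#' coordinates with `0 <= start < end`, and (if present) a strand column
#' restricted to `+`, `-`, `.`.
#'
#' @param x A data frame with `chrom`, `start`, `end` columns.
#' @param what Label used in error messages.
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x, what = "interval set") {
  if (!is.data.frame(x)) {
    stop(what, ": expected a data frame of intervals", call. = FALSE)
  }
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop(what, ": missing columns ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom) | !nzchar(x$chrom))) {
    stop(what, ": chromosome names must be non-empty", call. = FALSE)
  }
  if (any(is.na(x$start)) || any(is.na(x$end)) ||
      any(x$start != trunc(x$start)) || any(x$end != trunc(x$end))) {
    stop(what, ": coordinates must be non-missing integers", call. = FALSE)
  }
  bad <- which(x$start < 0 | x$start >= x$end)
  if (length(bad) > 0) {
    stop(what, ": invalid span on row ", bad[1], " (",
         x$chrom[bad[1]], ":", x$start[bad[1]], "-", x$end[bad[1]],
         "); need 0 <= start < end", call. = FALSE)
  }
  if ("strand" %in% names(x)) {
    ok <- x$strand %in% c("+", "-", ".") | is.na(x$strand)
    if (!all(ok)) {
      stop(what, ": strand must be one of '+', '-', '.'", call. = FALSE)
    }
  }
  invisible(x)
}

#' Check that intervals only name chromosomes present in a genome
#'
#' Chromosome naming is taken literally (no "chr" aliasing). A mismatch
#' between the chromosome universes of a genome and an interval set is a hard
#' error listing the orphan names, because a silently empty intersection is
#' the classic failure mode of this kind of pipeline.
#'
#' @param x Interval table.
#' @param chroms Character vector of known chromosome names (e.g.
#'   `names(genome)`).
#' @param what Label for the interval set, used in the error message.
#' @return `x`, invisibly.
#' @export
check_chrom_universe <- function(x, chroms, what = "interval set") {
  orphans <- setdiff(unique(x$chrom), chroms)
  if (length(orphans) > 0) {
    stop(what, " names chromosomes absent from the genome/annotation: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

# Stable (chrom, start, end) ordering used everywhere a sorted output is
# promised; ties keep input order so results are deterministic.
sort_intervals <- function(x) {
  if (nrow(x) == 0) return(x)
  x[order(x$chrom, x$start, x$end, method = "radix"), , drop = FALSE]
}
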