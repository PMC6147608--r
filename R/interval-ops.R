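#' Intersect two interval sets, reporting qualifying A intervals once
#'
#' Reimplements the `intersectBed -wa -u` semantics with the `-F` overlap
#' fraction anchored on the B feature: an A interval is returned iff some B
#' interval on the same chromosome overlaps it by at least
#' `min_b_fraction * length(B)` bp. With `min_b_fraction = 1` this is full
#' containment of the B feature (a B feature exactly coextensive with an A
#' interval counts as contained); a tiny positive value (e.g. `1e-9`)
#' reproduces plain >= 1 bp overlap. Each qualifying A interval appears
#' exactly once, with its original coordinates, in input order. Strand is
#' ignored: the comparisons are coordinate-only.
#'
#' @param a Interval table whose records are reported.
#' @param b Interval table providing the evidence features.
#' @param min_b_fraction Fraction in (0, 1] of each B feature's length that
#'   must overlap an A interval for the pair to count.
#' @return The qualifying rows of `a`, unchanged.
#' @examples
#' a <- genomic_interval("chr1", 100, 200)
#' b <- genomic_interval("chr1", 120, 128)
#' intersect_report_a(a, b, min_b_fraction = 1)
#' @export
intersect_report_a <- function(a, b, min_b_fraction = 1.0) {
  validate_intervals(a, "A")
  validate_intervals(b, "B")
  if (!is.numeric(min_b_fraction) || length(min_b_fraction) != 1 ||
      is.na(min_b_fraction) || min_b_fraction <= 0 || min_b_fraction > 1) {
    stop("min_b_fraction must be a single number in (0, 1]", call. = FALSE)
  }
  if (nrow(a) == 0 || nrow(b) == 0) return(a[integer(0), , drop = FALSE])
  keep <- logical(nrow(a))
  for (chr in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- which(a$chrom == chr)
    bi <- which(b$chrom == chr)
    # IRanges is 1-based closed; shift the half-open starts by one
    fo <- IRanges::findOverlaps(
      IRanges::IRanges(a$start[ai] + 1L, a$end[ai]),
      IRanges::IRanges(b$start[bi] + 1L, b$end[bi])
    )
    if (length(fo) == 0) next
    qa <- ai[S4Vectors::queryHits(fo)]
    qb <- bi[S4Vectors::subjectHits(fo)]
    ov <- pmin(a$end[qa], b$end[qb]) - pmax(a$start[qa], b$start[qb])
    need <- min_b_fraction * (b$end[qb] - b$start[qb])
    keep[unique(qa[ov >= need - 1e-9])] <- TRUE
  }
  a[keep, , drop = FALSE]
}

#' Merge an interval set into sorted, non-overlapping intervals
#'
#' Union-preserving: every covered base stays covered and no new base is
#' added. Abutting intervals (one's `end` equals the next one's `start`) are
#' merged. Name/score/strand annotations are dropped.
#'
#' @param x Interval table.
#' @return A tibble with columns `chrom`, `start`, `end`, sorted by
#'   (chrom, start).
#' @export
merge_intervals <- function(x) {
  validate_intervals(x, "merge input")
  if (nrow(x) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  x <- sort_intervals(x)
  new_run <- c(TRUE, x$chrom[-1] != x$chrom[-nrow(x)] |
                 x$start[-1] > cummax_by_chrom(x))
  grp <- cumsum(new_run)
  tibble::tibble(
    chrom = as.character(unname(tapply(x$chrom, grp, `[`, 1))),
    start = as.integer(unname(tapply(x$start, grp, min))),
    end = as.integer(unname(tapply(x$end, grp, max)))
  )
}

# running maximum of end coordinates within each chromosome, lagged by one,
# used to detect the start of a new merged run (strictly greater than the
# running end => gap; equal => abutting, merged)
cummax_by_chrom <- function(x) {
  ends <- numeric(nrow(x))
  for (chr in unique(x$chrom)) {
    i <- which(x$chrom == chr)
    ends[i] <- cummax(x$end[i])
  }
  ends[-length(ends)]
}

#' Find the nearest transcript to a query interval
#'
#' Distance is 0 when the query overlaps the transcript; otherwise it is the
#' gap in bp between the closest edges. Ties are broken by smaller transcript
#' start, then lexicographically smaller `transcript_id`. Transcripts on
#' other chromosomes are ineligible; if no transcript shares the query's
#' chromosome the result is absent (`NULL`) with a warning. Distance is
#' unsigned; the transcript's strand is carried along so callers can derive
#' orientation.
#'
#' @param query A single-row interval table (or anything with `chrom`,
#'   `start`, `end`).
#' @param transcripts Transcript table from [read_transcripts()].
#' @return A list with elements `transcript` (one-row tibble) and `distance`
#'   (non-negative integer), or `NULL` if no transcript shares the
#'   chromosome.
#' @export
nearest_transcript <- function(query, transcripts) {
  if (nrow(transcripts) == 0) {
    stop("transcript set is empty", call. = FALSE)
  }
  validate_intervals(query, "query")
  validate_intervals(transcripts, "transcripts")
  if (nrow(query) != 1) {
    stop("nearest_transcript expects a single query interval; see ",
         "annotate_nearest() for tables", call. = FALSE)
  }
  ann <- suppressWarnings(annotate_nearest(query, transcripts))
  if (is.na(ann$transcript_id[1])) {
    warning("no transcript on chromosome ", query$chrom[1], call. = FALSE)
    return(NULL)
  }
  tx <- transcripts[transcripts$transcript_id == ann$transcript_id[1], ,
                    drop = FALSE]
  list(transcript = tx, distance = ann$distance[1])
}

#' Annotate each interval with its nearest transcript
#'
#' Vectorised form of [nearest_transcript()] with the same distance and
#' tie-break rules; rows whose chromosome has no transcript get `NA`
#' annotations (with one warning).
#'
#' @param x Interval table.
#' @param transcripts Transcript table.
#' @return `x` with added columns `gene_id`, `transcript_id`,
#'   `transcript_strand`, `distance`.
#' @export
annotate_nearest <- function(x, transcripts) {
  if (nrow(transcripts) == 0) {
    stop("transcript set is empty", call. = FALSE)
  }
  validate_intervals(x, "query")
  validate_intervals(transcripts, "transcripts")
  n <- nrow(x)
  gene <- rep(NA_character_, n)
  tx <- rep(NA_character_, n)
  txs <- rep(NA_character_, n)
  dist <- rep(NA_integer_, n)
  tx_strand <- if ("strand" %in% names(transcripts)) {
    transcripts$strand
  } else {
    rep(".", nrow(transcripts))
  }
  for (i in seq_len(n)) {
    ti <- which(transcripts$chrom == x$chrom[i])
    if (length(ti) == 0) next
    d <- pmax(0L,
              pmax(x$start[i], transcripts$start[ti]) -
                pmin(x$end[i], transcripts$end[ti]))
    # tie-break: min distance, then smaller transcript start, then id
    o <- order(d, transcripts$start[ti], transcripts$transcript_id[ti],
               method = "radix")[1]
    gene[i] <- transcripts$gene_id[ti[o]]
    tx[i] <- transcripts$transcript_id[ti[o]]
    txs[i] <- tx_strand[ti[o]]
    dist[i] <- d[o]
  }
  if (anyNA(tx) && n > 0) {
    warning("no transcript on chromosome(s): ",
            paste(unique(x$chrom[is.na(tx)]), collapse = ", "),
            call. = FALSE)
  }
  out <- x
  out$gene_id <- gene
  out$transcript_id <- tx
  out$transcript_strand <- txs
  out$distance <- dist
  out
}
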