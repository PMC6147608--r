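# Independent brute-force oracles and fixture generators used across the
# suite. They share nothing with the package implementations beyond the input
# objects themselves.

DNA <- c("A", "C", "G", "T")

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
}

oracle_window_score <- function(mat, subseq) {
  idx <- match(strsplit(subseq, "", fixed = TRUE)[[1]], DNA)
  if (anyNA(idx)) return(NA_real_)
  tot <- 0
  for (j in seq_along(idx)) tot <- tot + unname(mat[idx[j], j])
  tot
}

# exhaustive O(L * W) enumeration of all windows on the requested strands
oracle_scan <- function(genome, p, fraction, strands = "both") {
  thr <- fraction * p$max_score
  W <- p$width
  rows <- list()
  for (chrom in names(genome)) {
    s <- genome[[chrom]]
    L <- nchar(s)
    if (L < W) next
    for (pos in 0:(L - W)) {
      win <- substr(s, pos + 1, pos + W)
      sc <- oracle_window_score(p$matrix, win)
      if (!is.na(sc) && sc >= thr) {
        rows[[length(rows) + 1]] <- data.frame(
          chrom = chrom, start = pos, end = pos + W, score = sc,
          strand = "+", stringsAsFactors = FALSE)
      }
      if (strands == "both") {
        sc <- oracle_window_score(p$matrix, oracle_revcomp(win))
        if (!is.na(sc) && sc >= thr) {
          rows[[length(rows) + 1]] <- data.frame(
            chrom = chrom, start = pos, end = pos + W, score = sc,
            strand = "-", stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start, out$strand, method = "radix"), ,
      drop = FALSE]
}

# all-pairs report-A intersection with fraction-of-B semantics
oracle_intersect <- function(a, b, frac) {
  keep <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov > 0 && ov >= frac * (b$end[j] - b$start[j]) - 1e-9) {
        keep[i] <- TRUE
        break
      }
    }
  }
  a[keep, , drop = FALSE]
}

# all-pairs minimum distance with the documented tie-break
oracle_nearest <- function(q, txs) {
  best <- NULL
  for (j in seq_len(nrow(txs))) {
    if (txs$chrom[j] != q$chrom) next
    d <- max(0L, max(q$start, txs$start[j]) - min(q$end, txs$end[j]))
    cand <- list(d = d, start = txs$start[j], id = txs$transcript_id[j],
                 gene = txs$gene_id[j])
    if (is.null(best) ||
        d < best$d ||
        (d == best$d && cand$start < best$start) ||
        (d == best$d && cand$start == best$start && cand$id < best$id)) {
      best <- cand
    }
  }
  best
}

# per-peak evaluation of the seven logical conditions, by brute force
oracle_conditions <- function(peak, peaks, hits, motif_classes,
                              motif_frac = 1.0) {
  any_overlap <- function(b) {
    any(b$chrom == peak$chrom & pmin(peak$end, b$end) -
          pmax(peak$start, b$start) > 0)
  }
  contained <- function(h) {
    any(h$chrom == peak$chrom & h$start >= peak$start - 1e-9 &
          pmin(peak$end, h$end) - pmax(peak$start, h$start) >=
            motif_frac * (h$end - h$start) - 1e-9)
  }
  out <- c(
    dll_chip = any_overlap(peaks$dll_chip),
    sp1_chip = any_overlap(peaks$sp1_chip),
    faire = any_overlap(peaks$faire)
  )
  for (cls in motif_classes) {
    out[[cls]] <- contained(hits[hits$factor_class == cls, , drop = FALSE])
  }
  out
}

rand_intervals <- function(n, chroms = c("chr1", "chr2", "chr3"),
                           max_pos = 1000L, max_len = 120L,
                           with_annot = FALSE) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  x <- tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                      start = start, end = start + len)
  if (with_annot) {
    x$name <- sprintf("iv%03d", seq_len(n))
    x$score <- round(stats::runif(n, 0, 100), 4)
    x$strand <- sample(c("+", "-", "."), n, replace = TRUE)
  }
  x
}

rand_pwm <- function(W, id = "rand", factor_class = "rand") {
  m <- matrix(stats::runif(4 * W, 0.05, 1), nrow = 4)
  pwm(m, id = id, factor_class = factor_class)
}

rand_genome <- function(lens, gc = 0.45) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  setNames(vapply(lens, function(L) {
    paste(sample(DNA, L, replace = TRUE, prob = p), collapse = "")
  }, character(1)), paste0("chr", seq_along(lens)))
}

# compact simulation used by unit tests (acceptance tests use the defaults)
small_sim_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chroms = 2L, chrom_length = 20000L,
         n_true_crms = 4L, n_decoys_per_pattern = 1L, n_transcripts = 10L),
    list(...))
  do.call(simulation_config, args)
}
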