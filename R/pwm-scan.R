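#' Construct a position weight matrix
#'
#' A PWM is a 4 x W matrix of non-negative base weights, rows in A,C,G,T
#' order. A window of width W is scored as the sum over positions of the
#' weight of the observed base. Count matrices are column-normalised to
#' probabilities; matrices whose columns already sum to 1 (within 1e-6) are
#' taken as probabilities. The attainable score range is
#' `min_score = sum(column minima)` to `max_score = sum(column maxima)`.
#'
#' @param matrix Numeric 4 x W matrix (counts or probabilities), rows A,C,G,T.
#' @param id Matrix identifier.
#' @param factor_class Factor class the matrix represents (e.g. `"dll"`,
#'   `"sp1"`, `"pan"`, `"mad"`); defaults to `id`.
#' @param normalize If `TRUE` (default), convert counts to probabilities.
#' @return An object of class `"pwm"`: a list with elements `id`,
#'   `factor_class`, `matrix`, `width`, `min_score`, `max_score`.
#' @examples
#' m <- matrix(c(8, 0, 0, 0, 0, 8, 0, 0), nrow = 4)
#' pwm(m, id = "toy")
#' @export
pwm <- function(matrix, id, factor_class = NULL, normalize = TRUE) {
  if (!is.matrix(matrix) || nrow(matrix) != 4 || ncol(matrix) < 1) {
    stop("PWM must be a 4 x W matrix with W >= 1", call. = FALSE)
  }
  if (any(is.na(matrix)) || any(matrix < 0)) {
    stop("PWM entries must be non-negative and non-missing", call. = FALSE)
  }
  sums <- colSums(matrix)
  if (any(sums <= 0)) {
    stop("PWM column ", which(sums <= 0)[1], " sums to zero", call. = FALSE)
  }
  if (normalize && any(abs(sums - 1) > 1e-6)) {
    matrix <- sweep(matrix, 2, sums, "/")
  }
  rownames(matrix) <- c("A", "C", "G", "T")
  structure(
    list(id = as.character(id),
         factor_class = as.character(factor_class %||% id),
         matrix = matrix,
         width = ncol(matrix),
         min_score = sum(apply(matrix, 2, min)),
         max_score = sum(apply(matrix, 2, max))),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$id, "(class", paste0(x$factor_class, ")"),
      "width", x$width, "\n")
  cat("score range [", format(x$min_score, digits = 4), ",",
      format(x$max_score, digits = 4), "]\n")
  print(round(x$matrix, 3))
  invisible(x)
}

#' Score one sequence window against a PWM
#'
#' For the minus strand the reverse complement of the window is scored, so the
#' score always refers to the motif read off the given strand while the window
#' coordinates stay on the forward strand. Windows containing `N` are
#' disqualified (return `NA`) rather than partially scored, to avoid
#' threshold-dependent artifacts at assembly gaps.
#'
#' @param pwm A [pwm] object.
#' @param subseq Nucleotide string of length `pwm$width` over `{A,C,G,T,N}`.
#' @param strand `"+"` or `"-"`.
#' @return The window score, or `NA` if the window contains `N`.
#' @export
window_score <- function(pwm, subseq, strand = "+") {
  stopifnot(inherits(pwm, "pwm"))
  strand <- match.arg(strand, c("+", "-"))
  if (nchar(subseq) != pwm$width) {
    stop("window length ", nchar(subseq), " != PWM width ", pwm$width,
         call. = FALSE)
  }
  s <- toupper(subseq)
  if (grepl("[^ACGTN]", s)) {
    stop("window contains characters outside {A,C,G,T,N}: ", s, call. = FALSE)
  }
  if (strand == "-") s <- reverse_complement(s)
  codes <- match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  if (anyNA(codes)) return(NA_real_)
  sum(pwm$matrix[cbind(codes, seq_len(pwm$width))])
}

#' Reverse-complement a nucleotide string
#'
#' @param s String over `{A,C,G,T,N}` (case-insensitive).
#' @return The reverse complement, uppercase.
#' @export
reverse_complement <- function(s) {
  vapply(s, function(x) {
    chartr("ACGTNacgtn", "TGCANTGCAN",
           paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Convert a percent-of-maximum fraction to an absolute score threshold
#'
#' The default convention is `fraction * max_score`, i.e. percent of the
#' highest attainable score — the natural reading of "minimum score of 80%"
#' for a scan over probability matrices. The alternative `"range"` convention
#' `min_score + fraction * (max_score - min_score)` is provided for
#' sensitivity analysis; the two coincide at `fraction = 1` and whenever
#' `min_score = 0`.
#'
#' @param pwm A [pwm] object.
#' @param fraction Number in (0, 1].
#' @param convention `"max_score"` (default) or `"range"`.
#' @return Absolute score threshold.
#' @export
threshold_from_fraction <- function(pwm, fraction,
                                    convention = c("max_score", "range")) {
  stopifnot(inherits(pwm, "pwm"))
  convention <- match.arg(convention)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      is.na(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be a single number in (0, 1]", call. = FALSE)
  }
  if (convention == "max_score") {
    fraction * pwm$max_score
  } else {
    pwm$min_score + fraction * (pwm$max_score - pwm$min_score)
  }
}

#' Scan a genome for PWM hits above a percent-of-maximum threshold
#'
#' Every window position on every chromosome is evaluated on the requested
#' strand(s); a hit is emitted iff its score is at least
#' `min_score_fraction * max_score` (or the range convention, see
#' [threshold_from_fraction()]). Hit coordinates always refer to the forward
#' strand; minus-strand hits are the windows whose reverse complement scores
#' above threshold. Overlapping and abutting hits are all reported. Windows
#' containing `N` never produce hits.
#'
#' @param genome Named character vector as returned by [read_fasta()].
#' @param pwm A [pwm] object.
#' @param min_score_fraction Score threshold as a fraction in (0, 1] of the
#'   maximum attainable score; default 0.80.
#' @param strands `"both"` (default) or `"forward"`.
#' @param convention Threshold convention, see [threshold_from_fraction()].
#' @return A tibble of motif hits sorted by (chrom, start, strand), with
#'   columns `chrom`, `start`, `end`, `name` (= `pwm_id`), `score`, `strand`,
#'   `pwm_id`, `factor_class`. Each interval has length `pwm$width`.
#' @examples
#' p <- pwm(matrix(c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1),
#'          nrow = 4), id = "acgt")
#' scan_sequence(c(chr1 = "ACGT"), p, min_score_fraction = 1,
#'               strands = "forward")
#' @export
scan_sequence <- function(genome, pwm, min_score_fraction = 0.80,
                          strands = c("both", "forward"),
                          convention = c("max_score", "range")) {
  stopifnot(inherits(pwm, "pwm"))
  strands <- match.arg(strands)
  convention <- match.arg(convention)
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    stop("genome must be a named character vector", call. = FALSE)
  }
  threshold <- threshold_from_fraction(pwm, min_score_fraction, convention)
  W <- pwm$width
  if (all(nchar(genome) < W)) {
    warning("PWM width ", W, " exceeds every chromosome length; no windows",
            call. = FALSE)
  }
  # Scoring the reverse complement of each forward window is equivalent to
  # scoring the forward window with the column-reversed, row-complemented
  # matrix, so both strands are scanned in forward coordinates.
  mats <- list(`+` = pwm$matrix)
  if (strands == "both") {
    mats$`-` <- pwm$matrix[c(4, 3, 2, 1), rev(seq_len(W)), drop = FALSE]
  }
  out <- list()
  for (chrom in names(genome)) {
    L <- nchar(genome[[chrom]])
    if (L < W) next
    codes <- match(strsplit(genome[[chrom]], "", fixed = TRUE)[[1]],
                   c("A", "C", "G", "T"))
    n_win <- L - W + 1L
    starts0 <- seq_len(n_win) - 1L
    for (st in names(mats)) {
      m <- mats[[st]]
      scores <- numeric(n_win)
      ok <- rep(TRUE, n_win)
      for (j in seq_len(W)) {
        cj <- codes[starts0 + j]
        ok <- ok & !is.na(cj)
        cj[is.na(cj)] <- 1L
        scores <- scores + m[cbind(cj, j)]
      }
      hit <- ok & scores >= threshold
      if (any(hit)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          chrom = chrom,
          start = starts0[hit],
          end = starts0[hit] + W,
          name = pwm$id,
          score = scores[hit],
          strand = st,
          pwm_id = pwm$id,
          factor_class = pwm$factor_class
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          score = numeric(), strand = character(),
                          pwm_id = character(), factor_class = character()))
  }
  res <- dplyr::bind_rows(out)
  res[order(res$chrom, res$start, res$strand, method = "radix"), ]
}

#' Scan a genome with several PWMs
#'
#' Convenience wrapper running [scan_sequence()] for each matrix and binding
#' the results; used by the pipeline so that matrices of the same factor
#' class are OR-combined at the hit level.
#'
#' @param genome Named character vector of sequences.
#' @param pwms List of [pwm] objects.
#' @inheritParams scan_sequence
#' @return A tibble of hits from all matrices.
#' @export
scan_pwms <- function(genome, pwms, min_score_fraction = 0.80,
                      strands = c("both", "forward"),
                      convention = c("max_score", "range")) {
  strands <- match.arg(strands)
  convention <- match.arg(convention)
  dplyr::bind_rows(lapply(pwms, function(p) {
    scan_sequence(genome, p, min_score_fraction, strands, convention)
  }))
}
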