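#' Read a multi-record FASTA file into a genome
#'
#' The genome is represented as a named character vector mapping chromosome
#' name to an uppercase nucleotide string over `{A,C,G,T,N}`. The chromosome
#' name is the first whitespace-delimited token of each header. Characters
#' outside the alphabet (IUPAC ambiguity codes, gaps) are mapped to `N` with a
#' warning, since downstream scanning defines how `N` is handled.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgt", "ACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  lines <- read_text_lines(path, "FASTA")
  headers <- startsWith(lines, ">")
  if (!any(headers)) {
    stop("FASTA format error at line 1: no '>' header found in ", path,
         call. = FALSE)
  }
  first_data <- which(!headers & nzchar(trimws(lines)))
  if (length(first_data) > 0 && first_data[1] < which(headers)[1]) {
    stop("FASTA format error at line ", first_data[1],
         ": sequence data before any '>' header", call. = FALSE)
  }
  rec <- cumsum(headers)
  nm <- vapply(lines[headers], function(h) {
    strsplit(trimws(sub("^>", "", h)), "\\s+")[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  if (any(is.na(nm) | !nzchar(nm))) {
    stop("FASTA format error: empty sequence name in header", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop("FASTA format error: duplicate sequence name '",
         nm[duplicated(nm)][1], "'", call. = FALSE)
  }
  seqs <- vapply(seq_along(nm), function(i) {
    toupper(paste0(gsub("\\s", "", lines[!headers & rec == i]),
                   collapse = ""))
  }, character(1))
  names(seqs) <- nm
  n_bad <- sum(vapply(seqs, function(s) {
    nchar(gsub("[ACGTN]", "", s))
  }, integer(1)))
  if (n_bad > 0) {
    warning(n_bad, " non-ACGTN character(s) mapped to N while reading ",
            path, call. = FALSE)
    seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), character(1))
  }
  if (any(nchar(seqs) == 0)) {
    warning("zero-length sequence(s) in ", path, ": ",
            paste(nm[nchar(seqs) == 0], collapse = ", "), call. = FALSE)
  }
  seqs
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    n <- nchar(s)
    if (n > 0) {
      starts <- seq(1L, n, by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
    }
  }
  invisible(path)
}

#' Read a BED6 or ENCODE narrowPeak file
#'
#' BED coordinates are 0-based half-open and are kept as-is. `'.'`
#' placeholders yield `NA` in the optional columns, and the ENCODE sentinel
#' `-1` in the narrowPeak summit column yields an absent (`NA`)
#' `summit_offset`. Input row order is preserved.
#'
#' @param path Path to a tab-delimited file.
#' @param kind `"bed6"` (3 to 6 columns) or `"narrowpeak"` (exactly 10).
#' @param source Optional label recorded in a `source` column (used for peak
#'   files, e.g. `"dll_chip"`, `"sp1_chip"`, `"faire"`).
#' @return A tibble of intervals. For `kind = "narrowpeak"` the extra columns
#'   are `signal`, `p_score`, `q_score` and `summit_offset` (offset of the
#'   peak summit from `start`, in bp).
#' @export
read_bed <- function(path, kind = c("bed6", "narrowpeak"), source = NULL) {
  kind <- match.arg(kind)
  lines <- read_text_lines(path, "BED", allow_empty = TRUE)
  keep <- nzchar(trimws(lines)) & !grepl("^(#|track\\b|browser\\b)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) {
    out <- genomic_interval(character(), integer(), integer())
    if (kind == "narrowpeak") {
      out$signal <- numeric(0); out$p_score <- numeric(0)
      out$q_score <- numeric(0); out$summit_offset <- integer(0)
    }
    if (!is.null(source)) out$source <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  want <- if (kind == "bed6") 3:6 else 10L
  bad <- which(!(ncol %in% want))
  if (length(bad) > 0) {
    stop("BED format error at line ", lineno[bad[1]], " of ", path, ": ",
         ncol[bad[1]], " columns (expected ",
         if (kind == "bed6") "3-6" else "10", ")", call. = FALSE)
  }
  col <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default,
           character(1))
  }
  start <- parse_int_col(col(2), lineno, path, "start")
  end <- parse_int_col(col(3), lineno, path, "end")
  bad <- which(start < 0 | start >= end)
  if (length(bad) > 0) {
    stop("BED format error at line ", lineno[bad[1]], " of ", path,
         ": invalid span ", start[bad[1]], "-", end[bad[1]], call. = FALSE)
  }
  out <- tibble::tibble(
    chrom = col(1),
    start = start,
    end = end,
    name = dot_na(col(4)),
    score = suppressWarnings(as.numeric(dot_na(col(5)))),
    strand = ifelse(is.na(dot_na(col(6))), ".", col(6))
  )
  validate_intervals(out, paste0("BED file ", path))
  if (kind == "narrowpeak") {
    out$signal <- parse_num_col(col(7), lineno, path, "signalValue")
    out$p_score <- parse_num_col(col(8), lineno, path, "pValue")
    out$q_score <- parse_num_col(col(9), lineno, path, "qValue")
    summit <- parse_int_col(col(10), lineno, path, "peak")
    summit[summit < 0] <- NA_integer_  # ENCODE -1 sentinel: summit absent
    bad <- which(!is.na(summit) & summit >= (out$end - out$start))
    if (length(bad) > 0) {
      stop("narrowPeak format error at line ", lineno[bad[1]], " of ", path,
           ": summit offset outside the peak", call. = FALSE)
    }
    out$summit_offset <- summit
  }
  if (!is.null(source)) out$source <- source
  out
}

#' Write intervals as BED6
#'
#' Deterministic field formatting: integer-valued scores are written without
#' decimals, fractional scores with four decimals, missing optional fields as
#' `'.'`. Round-trips through [read_bed()] losslessly for the fields BED6
#' carries (given scores representable at that precision).
#'
#' @param x Interval table (extra columns are ignored).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x, "write_bed input")
  nm <- if ("name" %in% names(x)) x$name else NA_character_
  sc <- if ("score" %in% names(x)) x$score else NA_real_
  st <- if ("strand" %in% names(x)) x$strand else "."
  lines <- paste(x$chrom, format_bed_int(x$start), format_bed_int(x$end),
                 ifelse(is.na(nm), ".", nm), format_bed_score(sc),
                 ifelse(is.na(st), ".", st), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a transcript annotation
#'
#' For `kind = "gtf_minimal"` only rows whose feature type is `transcript`
#' are consumed; their 1-based inclusive GTF coordinates are converted to the
#' package's 0-based half-open convention, and the `gene_id` and
#' `transcript_id` attributes are required. For `kind = "bed"` coordinates
#' are taken as-is; the name column supplies the IDs, either as
#' `"gene_id|transcript_id"` or as a single ID used for both. BED rows with
#' more than six columns (e.g. BED12) use the first six, with a warning.
#'
#' @param path Path to the annotation file.
#' @param kind `"bed"` or `"gtf_minimal"`.
#' @return A tibble with columns `chrom`, `start`, `end`, `transcript_id`,
#'   `gene_id`, `strand`. `transcript_id` must be unique.
#' @export
read_transcripts <- function(path, kind = c("bed", "gtf_minimal")) {
  kind <- match.arg(kind)
  if (kind == "bed") {
    lines <- read_text_lines(path, "BED", allow_empty = TRUE)
    keep <- nzchar(trimws(lines)) & !grepl("^(#|track\\b|browser\\b)", lines)
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    if (any(lengths(fields) > 6)) {
      warning("transcript BED has rows with >6 columns; using the first six",
              call. = FALSE)
      fields <- lapply(fields, function(f) f[seq_len(min(6, length(f)))])
      tmp <- tempfile(fileext = ".bed")
      writeLines(vapply(fields, paste, character(1), collapse = "\t"), tmp)
      bed <- read_bed(tmp, "bed6")
      unlink(tmp)
    } else {
      bed <- read_bed(path, "bed6")
    }
    if (nrow(bed) > 0 && any(is.na(bed$name))) {
      stop("transcript BED format error: missing name (transcript_id) field",
           call. = FALSE)
    }
    has_pipe <- grepl("|", bed$name, fixed = TRUE)
    gene <- ifelse(has_pipe, sub("\\|.*$", "", bed$name), bed$name)
    tx <- ifelse(has_pipe, sub("^[^|]*\\|", "", bed$name), bed$name)
    out <- tibble::tibble(chrom = bed$chrom, start = bed$start,
                          end = bed$end, transcript_id = tx, gene_id = gene,
                          strand = bed$strand)
  } else {
    lines <- read_text_lines(path, "GTF", allow_empty = TRUE)
    keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
    lineno <- which(keep)
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 9)
    if (length(bad) > 0) {
      stop("GTF format error at line ", lineno[bad[1]], " of ", path,
           ": fewer than 9 columns", call. = FALSE)
    }
    is_tx <- vapply(fields, function(f) f[3] == "transcript", logical(1))
    fields <- fields[is_tx]
    lineno <- lineno[is_tx]
    attr_val <- function(attrs, key, i) {
      m <- regmatches(attrs, regexec(paste0(key, '\\s+"([^"]*)"'), attrs))[[1]]
      if (length(m) < 2) {
        stop("GTF format error at line ", lineno[i], " of ", path,
             ": missing required attribute ", key, call. = FALSE)
      }
      m[2]
    }
    n <- length(fields)
    out <- tibble::tibble(
      chrom = vapply(fields, `[`, character(1), 1),
      # GTF is 1-based inclusive; convert to 0-based half-open
      start = parse_int_col(vapply(fields, `[`, character(1), 4),
                            lineno, path, "start") - 1L,
      end = parse_int_col(vapply(fields, `[`, character(1), 5),
                          lineno, path, "end"),
      transcript_id = vapply(seq_len(n), function(i)
        attr_val(fields[[i]][9], "transcript_id", i), character(1)),
      gene_id = vapply(seq_len(n), function(i)
        attr_val(fields[[i]][9], "gene_id", i), character(1)),
      strand = vapply(fields, `[`, character(1), 7)
    )
  }
  validate_intervals(out, paste0("transcript annotation ", path))
  if (anyDuplicated(out$transcript_id)) {
    stop("transcript annotation error: duplicate transcript_id '",
         out$transcript_id[duplicated(out$transcript_id)][1], "'",
         call. = FALSE)
  }
  out
}

#' Read a position weight matrix
#'
#' Accepts JASPAR single-matrix text (`A [ 8 0 ... ]` rows, optional `>`
#' header), a minimal MEME motif block (`MOTIF` line plus a
#' `letter-probability matrix` block with positions as rows), or a bare 4-row
#' TSV (rows in A,C,G,T order, optional row labels). Count matrices are
#' column-normalised to probabilities; probability matrices are accepted if
#' every column sums to 1 within 1e-6.
#'
#' @param path Path to the matrix file.
#' @param dialect `"jaspar"`, `"meme_minimal"` or `"tsv"`.
#' @param id Matrix identifier; defaults to the ID found in the file, else
#'   the file name.
#' @param factor_class Factor class label attached to hits (e.g. `"dll"`).
#' @return A [pwm] object.
#' @export
read_pwm <- function(path, dialect = c("jaspar", "meme_minimal", "tsv"),
                     id = NULL, factor_class = NULL) {
  dialect <- match.arg(dialect)
  lines <- read_text_lines(path, "PWM", allow_empty = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  file_id <- NULL
  if (dialect == "jaspar") {
    if (length(lines) > 0 && startsWith(lines[1], ">")) {
      file_id <- strsplit(trimws(sub("^>", "", lines[1])), "\\s+")[[1]][1]
      lines <- lines[-1]
    }
    if (length(lines) < 4) {
      stop("PWM format error in ", path, ": expected 4 base rows",
           call. = FALSE)
    }
    rows <- lapply(lines[1:4], function(l) {
      l <- trimws(l)
      base <- NA_character_
      if (grepl("^[ACGTacgt]\\b", l)) {
        base <- toupper(substr(l, 1, 1))
        l <- sub("^[ACGTacgt]", "", l)
      }
      nums <- parse_number_row(gsub("[][]", " ", l), path)
      list(base = base, nums = nums)
    })
    bases <- vapply(rows, `[[`, character(1), "base")
    nums <- lapply(rows, `[[`, "nums")
    if (length(unique(lengths(nums))) != 1) {
      stop("PWM format error in ", path, ": base rows have unequal widths",
           call. = FALSE)
    }
    mat <- do.call(rbind, nums)
    if (!any(is.na(bases))) {
      if (!setequal(bases, c("A", "C", "G", "T"))) {
        stop("PWM format error in ", path, ": row labels must be A,C,G,T",
             call. = FALSE)
      }
      mat <- mat[match(c("A", "C", "G", "T"), bases), , drop = FALSE]
    }
  } else if (dialect == "meme_minimal") {
    motif_line <- grep("^MOTIF\\b", lines, value = TRUE)
    if (length(motif_line) > 0) {
      file_id <- strsplit(trimws(motif_line[1]), "\\s+")[[1]][2]
    }
    hdr <- grep("^letter-probability matrix", lines)
    if (length(hdr) != 1) {
      stop("PWM format error in ", path,
           ": expected one 'letter-probability matrix' block", call. = FALSE)
    }
    body <- lines[(hdr + 1):length(lines)]
    body <- body[grepl("^[-0-9. \teE+]+$", trimws(body)) & nzchar(trimws(body))]
    if (length(body) == 0) {
      stop("PWM format error in ", path, ": empty probability matrix",
           call. = FALSE)
    }
    pos_rows <- lapply(body, parse_number_row, path = path)
    if (any(lengths(pos_rows) != 4)) {
      stop("PWM format error in ", path,
           ": each matrix row must have 4 values (A C G T)", call. = FALSE)
    }
    mat <- t(do.call(rbind, pos_rows))  # positions-as-rows -> bases-as-rows
  } else {
    if (length(lines) != 4) {
      stop("PWM format error in ", path, ": TSV dialect needs exactly 4 rows",
           call. = FALSE)
    }
    rows <- lapply(lines, function(l) {
      l <- trimws(l)
      if (grepl("^[ACGTacgt][\t ]", l)) l <- sub("^[ACGTacgt]", "", l)
      parse_number_row(l, path)
    })
    if (length(unique(lengths(rows))) != 1) {
      stop("PWM format error in ", path, ": rows have unequal widths",
           call. = FALSE)
    }
    mat <- do.call(rbind, rows)
  }
  if (!is.matrix(mat) || nrow(mat) != 4 || ncol(mat) < 1) {
    stop("PWM format error in ", path, ": expected a 4-row matrix with >= 1 column",
         call. = FALSE)
  }
  pwm(mat, id = id %||% file_id %||% basename(path),
      factor_class = factor_class)
}

#' Write a PWM in JASPAR single-matrix text
#'
#' @param x A [pwm] object.
#' @param path Output path.
#' @param digits Decimal places for the probabilities.
#' @return `path`, invisibly.
#' @export
write_pwm_jaspar <- function(x, path, digits = 6L) {
  stopifnot(inherits(x, "pwm"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0(">", x$id), con)
  for (i in 1:4) {
    writeLines(paste0(c("A", "C", "G", "T")[i], " [ ",
                      paste(formatC(x$matrix[i, ], format = "f",
                                    digits = digits), collapse = " "),
                      " ]"), con)
  }
  invisible(path)
}

# --- internal helpers -------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

read_text_lines <- function(path, label, allow_empty = FALSE) {
  if (!file.exists(path)) {
    stop(label, " file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  if (!allow_empty && (length(lines) == 0 || all(!nzchar(trimws(lines))))) {
    stop(label, " format error: ", path, " is empty", call. = FALSE)
  }
  lines
}

dot_na <- function(x) ifelse(x == "." | x == "" | is.na(x), NA_character_, x)

parse_int_col <- function(x, lineno, path, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | v != trunc(v))
  if (length(bad) > 0) {
    stop("format error at line ", lineno[bad[1]], " of ", path,
         ": non-integer ", what, " '", x[bad[1]], "'", call. = FALSE)
  }
  as.integer(v)
}

parse_num_col <- function(x, lineno, path, what) {
  out <- rep(NA_real_, length(x))
  idx <- !is.na(dot_na(x))
  v <- suppressWarnings(as.numeric(x[idx]))
  if (any(is.na(v))) {
    stop("format error in ", path, ": non-numeric ", what, call. = FALSE)
  }
  out[idx] <- v
  out
}

parse_number_row <- function(l, path) {
  toks <- strsplit(trimws(l), "[\t ]+")[[1]]
  toks <- toks[nzchar(toks)]
  v <- suppressWarnings(as.numeric(toks))
  if (length(v) == 0 || any(is.na(v))) {
    stop("PWM format error in ", path, ": non-numeric matrix row", call. = FALSE)
  }
  v
}

format_bed_int <- function(x) format(x, scientific = FALSE, trim = TRUE)

format_bed_score <- function(x) {
  out <- rep(".", length(x))
  ok <- !is.na(x)
  whole <- ok & x == trunc(x)
  out[whole] <- format(x[whole], scientific = FALSE, trim = TRUE)
  frac <- ok & !whole
  out[frac] <- formatC(x[frac], format = "f", digits = 4)
  out
}
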