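#' Configure the candidate-CRM criteria
#'
#' A candidate CRM is an anchor peak that (1) overlaps every required peak
#' set, (2) fully contains at least one motif hit of every required factor
#' class, and (3) is annotated with its nearest transcript. The anchor peak
#' set supplies the reported coordinates throughout the sequential
#' intersection, mirroring a `bedtools intersect -wa -u` chain that always
#' returns the coordinates of the initial file.
#'
#' Peak-vs-peak steps default to plain >= 1 bp overlap (`min_b_fraction =
#' 1e-9`); motif steps default to full containment (`min_b_fraction = 1`).
#' Both are configurable per step by passing named numeric vectors.
#'
#' @param anchor Name of the peak set whose coordinates are reported
#'   (default `"dll_chip"`). Must not also appear in `peak_requirements`.
#' @param peak_requirements Required peak sets: a character vector (default
#'   overlap fraction) or a named numeric vector of per-step
#'   `min_b_fraction` values, e.g. `c(sp1_chip = 1e-9, faire = 1e-9)`.
#' @param motif_requirements Required motif classes: a character vector
#'   (full containment) or a named numeric vector of per-step
#'   `min_b_fraction` values, e.g. `c(dll = 1, sp1 = 1, pan = 1, mad = 1)`.
#'   Must be non-empty.
#' @param min_score_fraction PWM score threshold as a fraction of the
#'   maximum attainable score; default 0.80.
#' @param strands Scanning mode, `"both"` (default) or `"forward"`.
#' @param threshold_convention See [threshold_from_fraction()].
#' @return A list of class `"criteria_config"`.
#' @export
criteria_config <- function(anchor = "dll_chip",
                            peak_requirements = c(sp1_chip = 1e-9,
                                                  faire = 1e-9),
                            motif_requirements = c(dll = 1, sp1 = 1,
                                                   pan = 1, mad = 1),
                            min_score_fraction = 0.80,
                            strands = c("both", "forward"),
                            threshold_convention = c("max_score", "range")) {
  peak_requirements <- as_step_fractions(peak_requirements, 1e-9,
                                         "peak_requirements")
  motif_requirements <- as_step_fractions(motif_requirements, 1.0,
                                          "motif_requirements")
  if (length(motif_requirements) == 0) {
    stop("motif_requirements must name at least one factor class",
         call. = FALSE)
  }
  if (anchor %in% names(peak_requirements)) {
    stop("anchor '", anchor, "' must not appear in peak_requirements",
         call. = FALSE)
  }
  structure(
    list(anchor = anchor,
         peak_requirements = peak_requirements,
         motif_requirements = motif_requirements,
         min_score_fraction = min_score_fraction,
         strands = match.arg(strands),
         threshold_convention = match.arg(threshold_convention)),
    class = "criteria_config"
  )
}

as_step_fractions <- function(x, default, what) {
  if (is.character(x)) {
    x <- stats::setNames(rep(default, length(x)), x)
  }
  if (length(x) == 0) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(x)) || any(!nzchar(names(x))) ||
      !is.numeric(x) || any(is.na(x) | x <= 0 | x > 1)) {
    stop(what, " must be a character vector or a named numeric vector of ",
         "fractions in (0, 1]", call. = FALSE)
  }
  x
}

#' Run the sequential candidate-CRM intersection
#'
#' Step 1 filters the anchor peaks by overlap with each required peak set;
#' step 2 sequentially filters the survivors by containment of at least one
#' motif hit per required factor class (multiple matrices of a class are
#' OR-combined); step 3 annotates each survivor with its nearest transcript.
#' Every filtering step logs input count, output count and the requirement
#' applied. Output is sorted by (chrom, start) and deterministic given the
#' inputs and config.
#'
#' @param genome Named character vector of sequences ([read_fasta()]).
#' @param peaks Named list of peak tables; must contain the anchor and every
#'   set named in `config$peak_requirements`.
#' @param pwms List of [pwm] objects covering every required factor class.
#' @param transcripts Transcript table ([read_transcripts()]).
#' @param config A [criteria_config()].
#' @param motif_hits Optional precomputed hit table from [scan_pwms()] run
#'   with the same scan settings (used to avoid re-scanning across config
#'   variants); when supplied the genome is not re-scanned.
#' @param verbose Log the filtering funnel via `message()`.
#' @return A tibble of candidate CRMs: the surviving anchor-peak rows plus
#'   per-class contained-hit counts (`n_<class>`), peak-support flags
#'   (`has_<set>`), and `gene_id`, `transcript_id`, `transcript_strand`,
#'   `distance` columns.
#' @export
run_crm_pipeline <- function(genome, peaks, pwms, transcripts,
                             config = criteria_config(), motif_hits = NULL,
                             verbose = TRUE) {
  stopifnot(inherits(config, "criteria_config"))
  say <- function(...) if (verbose) message(...)
  needed <- c(config$anchor, names(config$peak_requirements))
  missing_peaks <- setdiff(needed, names(peaks))
  if (length(missing_peaks) > 0) {
    stop("missing required peak set(s): ",
         paste(missing_peaks, collapse = ", "), call. = FALSE)
  }
  if (is.null(transcripts)) stop("missing transcripts", call. = FALSE)
  classes <- vapply(pwms, function(p) p$factor_class, character(1))
  missing_classes <- setdiff(names(config$motif_requirements), classes)
  if (length(missing_classes) > 0) {
    stop("no PWM supplied for required factor class(es): ",
         paste(missing_classes, collapse = ", "), call. = FALSE)
  }
  if (is.null(motif_hits)) {
    if (is.null(genome)) stop("missing genome", call. = FALSE)
    for (nm in needed) {
      check_chrom_universe(peaks[[nm]], names(genome), paste0("peak set ", nm))
    }
    check_chrom_universe(transcripts, names(genome), "transcripts")
    motif_hits <- scan_pwms(genome, pwms, config$min_score_fraction,
                            config$strands, config$threshold_convention)
  }

  cand <- peaks[[config$anchor]]
  say("anchor ", config$anchor, ": ", nrow(cand), " peaks")
  for (src in names(config$peak_requirements)) {
    frac <- config$peak_requirements[[src]]
    n_in <- nrow(cand)
    cand <- intersect_report_a(cand, peaks[[src]], frac)
    say("require overlap with ", src, " (min_b_fraction=", frac, "): ",
        n_in, " -> ", nrow(cand))
  }
  for (cls in names(config$motif_requirements)) {
    frac <- config$motif_requirements[[cls]]
    hits_cls <- motif_hits[motif_hits$factor_class == cls, , drop = FALSE]
    n_in <- nrow(cand)
    cand <- intersect_report_a(cand, hits_cls, frac)
    say("require contained ", cls, " motif (min_b_fraction=", frac, "): ",
        n_in, " -> ", nrow(cand))
  }
  cand <- sort_intervals(cand)

  for (cls in names(config$motif_requirements)) {
    hits_cls <- motif_hits[motif_hits$factor_class == cls, , drop = FALSE]
    cand[[paste0("n_", cls)]] <-
      count_contained(cand, hits_cls, config$motif_requirements[[cls]])
  }
  for (src in names(config$peak_requirements)) {
    qualifies <- intersect_report_a(cand, peaks[[src]],
                                    config$peak_requirements[[src]])
    cand[[paste0("has_", src)]] <-
      interval_key(cand) %in% interval_key(qualifies)
  }
  cand <- annotate_nearest(cand, transcripts)
  say("candidates: ", nrow(cand))
  cand
}

# per-A-row count of B features overlapping by >= frac * length(B)
count_contained <- function(a, b, frac) {
  n <- integer(nrow(a))
  if (nrow(a) == 0 || nrow(b) == 0) return(n)
  for (chr in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- which(a$chrom == chr)
    bi <- which(b$chrom == chr)
    fo <- IRanges::findOverlaps(
      IRanges::IRanges(a$start[ai] + 1L, a$end[ai]),
      IRanges::IRanges(b$start[bi] + 1L, b$end[bi])
    )
    if (length(fo) == 0) next
    qa <- ai[S4Vectors::queryHits(fo)]
    qb <- bi[S4Vectors::subjectHits(fo)]
    ov <- pmin(a$end[qa], b$end[qb]) - pmax(a$start[qa], b$start[qb])
    ok <- ov >= frac * (b$end[qb] - b$start[qb]) - 1e-9
    if (any(ok)) {
      tab <- table(qa[ok])
      n[as.integer(names(tab))] <- n[as.integer(names(tab))] + as.integer(tab)
    }
  }
  n
}

interval_key <- function(x) paste(x$chrom, x$start, x$end, sep = ":")

#' Run the full regulatory logic (with Sp1)
#'
#' Anchor peaks must overlap both the Sp1 ChIP and accessibility (FAIRE)
#' peak sets and fully contain at least one motif hit of each of the four
#' factor classes (Dll, Sp1, Pan, Mad) at the 80% percent-of-maximum score
#' threshold.
#'
#' @inheritParams run_crm_pipeline
#' @param ... Overrides passed to [criteria_config()].
#' @return A tibble of candidate CRMs; see [run_crm_pipeline()].
#' @export
run_full_logic <- function(genome, peaks, pwms, transcripts,
                           motif_hits = NULL, verbose = TRUE, ...) {
  run_crm_pipeline(genome, peaks, pwms, transcripts,
                   config = criteria_config(...),
                   motif_hits = motif_hits, verbose = verbose)
}

#' Run the relaxed regulatory logic (Sp1 excluded)
#'
#' Identical machinery with every Sp1 requirement removed: anchor peaks need
#' only overlap the accessibility peaks and contain Dll, Pan and Mad motif
#' hits. On identical inputs the result is by construction a superset of
#' [run_full_logic()].
#'
#' @inheritParams run_crm_pipeline
#' @param ... Overrides passed to [criteria_config()].
#' @return A tibble of candidate CRMs; see [run_crm_pipeline()].
#' @export
run_relaxed_logic <- function(genome, peaks, pwms, transcripts,
                              motif_hits = NULL, verbose = TRUE, ...) {
  cfg <- criteria_config(peak_requirements = c(faire = 1e-9),
                         motif_requirements = c(dll = 1, pan = 1, mad = 1),
                         ...)
  run_crm_pipeline(genome, peaks, pwms, transcripts, config = cfg,
                   motif_hits = motif_hits, verbose = verbose)
}

#' Write the candidate-CRM report
#'
#' Writes `<prefix>.tsv` (coordinates, nearest-gene annotation, per-class
#' contained-hit counts and peak-support flags), a companion `<prefix>.bed`
#' (BED6, name = anchor peak name or nearest gene), and `<prefix>.meta.txt`
#' echoing the configuration, package version and input record counts. All
#' formatting is deterministic so identical runs produce byte-identical
#' files.
#'
#' @param candidates Output of [run_crm_pipeline()].
#' @param prefix Output path prefix.
#' @param config Optional [criteria_config()] echoed into the metadata.
#' @param input_counts Optional named integer vector of input record counts
#'   echoed into the metadata.
#' @return Character vector of the paths written, invisibly.
#' @export
write_report <- function(candidates, prefix, config = NULL,
                         input_counts = NULL) {
  lead <- c("chrom", "start", "end", "gene_id", "transcript_id", "distance")
  extra <- setdiff(names(candidates),
                   c(lead, "name", "score", "strand", "source",
                     "transcript_strand"))
  cols <- c(lead, sort(extra))
  missing_cols <- setdiff(cols, names(candidates))
  for (mc in missing_cols) candidates[[mc]] <- NA
  tsv <- paste0(prefix, ".tsv")
  df <- as.data.frame(candidates[, cols, drop = FALSE])
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  bed <- paste0(prefix, ".bed")
  bed_rec <- candidates[, c("chrom", "start", "end"), drop = FALSE]
  nm <- if ("name" %in% names(candidates)) candidates$name else NA_character_
  if ("gene_id" %in% names(candidates)) {
    nm <- ifelse(is.na(nm), candidates$gene_id, nm)
  }
  bed_rec$name <- if (nrow(bed_rec) > 0) nm else character(0)
  bed_rec$score <- if ("score" %in% names(candidates)) {
    candidates$score
  } else {
    NA_real_
  }
  bed_rec$strand <- "."
  write_bed(bed_rec, bed)
  meta <- paste0(prefix, ".meta.txt")
  lines <- c(
    paste0("crmscan version: ",
           as.character(utils::packageVersion("crmscan"))),
    paste0("candidates: ", nrow(candidates))
  )
  if (!is.null(config)) {
    lines <- c(lines,
      paste0("anchor: ", config$anchor),
      paste0("peak_requirements: ",
             paste(names(config$peak_requirements),
                   config$peak_requirements, sep = "=", collapse = ", ")),
      paste0("motif_requirements: ",
             paste(names(config$motif_requirements),
                   config$motif_requirements, sep = "=", collapse = ", ")),
      paste0("min_score_fraction: ", config$min_score_fraction),
      paste0("strands: ", config$strands),
      paste0("threshold_convention: ", config$threshold_convention)
    )
  }
  if (!is.null(input_counts)) {
    lines <- c(lines, paste0("input ", names(input_counts), ": ",
                             input_counts))
  }
  writeLines(lines, meta)
  invisible(c(tsv = tsv, bed = bed, meta = meta))
}
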