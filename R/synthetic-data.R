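#' Configure the synthetic-genome generator
#'
#' The generator emulates the structure of the real inputs — a
#' multi-chromosome genome, three partially overlapping peak sets (two
#' ChIP-seq factors plus open chromatin), planted motif instances of four
#' factor classes inside and outside peaks, and a transcript map — with
#' known ground truth, so every pipeline stage can be verified without
#' external data.
#'
#' Each true CRM is a region covered identically by all three peak sets into
#' which one instance of every motif class is written, drawn column-wise from
#' the class PWM — at sharpness 1.0 this is the exact consensus, so recovery
#' is guaranteed; at lower sharpness instances can fall below the scan
#' threshold, which is what degrades recall. Each decoy
#' realises one specified condition-failure pattern: absent from one peak
#' file, or engineered to lack fully contained hits of one motif class (the
#' background under such a decoy is re-drawn until no chance hit of the
#' forbidden class survives at the scan threshold). The special pattern
#' `"straddle_dll"` plants the Dll instance straddling the peak's right edge
#' by 1 bp, so it is rejected under full containment but accepted under
#' >= 1 bp overlap.
#'
#' @param seed Integer seed; a single global seed governs all draws.
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param gc_content Background GC fraction (i.i.d. base draws).
#' @param pwm_specs Per factor class, a list with `consensus` (string) and
#'   `sharpness` (probability mass on the consensus base per column).
#' @param sharpness Optional override applied to every class's sharpness.
#' @param n_true_crms Number of planted true CRMs.
#' @param n_decoys_per_pattern Decoys generated for each failure pattern.
#' @param decoy_patterns List of failure patterns; each element is a
#'   character vector of failed conditions drawn from
#'   `{dll_chip, sp1_chip, faire, dll, sp1, pan, mad}`, or the string
#'   `"straddle_dll"`.
#' @param peak_width Length-2 integer vector, min/max peak width in bp.
#' @param peak_jitter Maximum bp by which the Sp1/FAIRE copies of a peak are
#'   expanded on each side (0 = identical intervals in all three files).
#' @param n_transcripts Number of transcripts, distributed round-robin over
#'   chromosomes.
#' @param scan_fraction Score threshold the truth is defined against (the
#'   pipeline default, 0.80).
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chroms = 3L,
                              chrom_length = 50000L,
                              gc_content = 0.41,
                              pwm_specs = list(
                                dll = list(consensus = "TTAATTAC",
                                           sharpness = 0.9),
                                sp1 = list(consensus = "GGGGGCGGGG",
                                           sharpness = 0.9),
                                pan = list(consensus = "CTTTGTTC",
                                           sharpness = 0.9),
                                mad = list(consensus = "GGCGCCAG",
                                           sharpness = 0.9)
                              ),
                              sharpness = NULL,
                              n_true_crms = 10L,
                              n_decoys_per_pattern = 2L,
                              decoy_patterns = list("sp1_chip", "faire",
                                                    "dll", "sp1", "pan",
                                                    "mad", "straddle_dll"),
                              peak_width = c(200L, 400L),
                              peak_jitter = 0L,
                              n_transcripts = 30L,
                              scan_fraction = 0.80) {
  if (!is.null(sharpness)) {
    pwm_specs <- lapply(pwm_specs, function(s) {
      s$sharpness <- sharpness
      s
    })
  }
  for (cls in names(pwm_specs)) {
    s <- pwm_specs[[cls]]
    if (is.null(s$consensus) || !nzchar(s$consensus) ||
        grepl("[^ACGT]", s$consensus)) {
      stop("pwm_specs$", cls, ": consensus must be a non-empty ACGT string",
           call. = FALSE)
    }
    if (is.null(s$sharpness) || s$sharpness <= 0.25 || s$sharpness > 1) {
      stop("pwm_specs$", cls, ": sharpness must be in (0.25, 1]",
           call. = FALSE)
    }
  }
  stopifnot(n_chroms >= 1, chrom_length >= 1000,
            gc_content > 0, gc_content < 1,
            n_true_crms >= 0, n_decoys_per_pattern >= 0,
            length(peak_width) == 2, peak_width[1] >= 1,
            peak_width[2] >= peak_width[1],
            peak_jitter >= 0, n_transcripts >= 0,
            scan_fraction > 0, scan_fraction <= 1)
  known <- c("dll_chip", "sp1_chip", "faire", names(pwm_specs))
  for (p in decoy_patterns) {
    if (identical(p, "straddle_dll")) next
    if (!all(p %in% known)) {
      stop("unknown condition in decoy pattern: ",
           paste(setdiff(p, known), collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
         chrom_length = as.integer(chrom_length), gc_content = gc_content,
         pwm_specs = pwm_specs, n_true_crms = as.integer(n_true_crms),
         n_decoys_per_pattern = as.integer(n_decoys_per_pattern),
         decoy_patterns = decoy_patterns,
         peak_width = as.integer(peak_width),
         peak_jitter = as.integer(peak_jitter),
         n_transcripts = as.integer(n_transcripts),
         scan_fraction = scan_fraction),
    class = "simulation_config"
  )
}

consensus_pwm <- function(consensus, sharpness, id, factor_class) {
  bases <- strsplit(consensus, "", fixed = TRUE)[[1]]
  W <- length(bases)
  m <- matrix((1 - sharpness) / 3, nrow = 4, ncol = W)
  m[cbind(match(bases, c("A", "C", "G", "T")), seq_len(W))] <- sharpness
  pwm(m, id = id, factor_class = factor_class)
}

#' Generate a seeded synthetic benchmark corpus
#'
#' Draws an i.i.d. background genome at the configured GC content, plants
#' true CRMs and decoys (see [simulation_config()]), builds the three peak
#' tables, the transcript map and the PWMs, and records the ground truth.
#' All output is deterministic given the seed: two runs with the same config
#' produce byte-identical files.
#'
#' @param config A [simulation_config()].
#' @param outdir Optional directory; when given, writes `genome.fa`,
#'   `dll_chip.bed`, `sp1_chip.bed`, `faire.bed`, `transcripts.bed`
#'   (names `gene_id|transcript_id`), one JASPAR-format `pwm_<class>.txt`
#'   per class, and `truth.tsv`.
#' @return A list with elements `genome` (named character vector), `peaks`
#'   (named list of tibbles `dll_chip`, `sp1_chip`, `faire`), `transcripts`,
#'   `pwms` (list of [pwm] objects), `truth` (see [write_truth()]), `config`,
#'   and `paths` when `outdir` was given.
#' @export
simulate_crm_data <- function(config = simulation_config(), outdir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  classes <- names(config$pwm_specs)
  pwms <- lapply(classes, function(cls) {
    consensus_pwm(config$pwm_specs[[cls]]$consensus,
                  config$pwm_specs[[cls]]$sharpness,
                  id = paste0("syn_", cls), factor_class = cls)
  })
  names(pwms) <- classes
  max_w <- max(vapply(pwms, function(p) p$width, integer(1)))
  base_prob <- c((1 - config$gc_content) / 2, config$gc_content / 2,
                 config$gc_content / 2, (1 - config$gc_content) / 2)
  chrom_names <- paste0("chr", seq_len(config$n_chroms))
  seqs <- lapply(chrom_names, function(x) {
    sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE,
           prob = base_prob)
  })
  names(seqs) <- chrom_names

  # region plan: true CRMs first, then decoys per pattern
  plan <- list()
  for (i in seq_len(config$n_true_crms)) {
    plan[[length(plan) + 1L]] <- list(name = sprintf("crm_%03d", i),
                                      fails = character(0),
                                      straddle = FALSE)
  }
  for (p in config$decoy_patterns) {
    straddle <- identical(p, "straddle_dll")
    fails <- if (straddle) "dll" else p
    for (k in seq_len(config$n_decoys_per_pattern)) {
      plan[[length(plan) + 1L]] <- list(
        name = sprintf("decoy_%s_%02d", paste(fails, collapse = "."), k),
        fails = fails, straddle = straddle)
      if (straddle) {
        plan[[length(plan)]]$name <- sprintf("decoy_straddle_dll_%02d", k)
      }
    }
  }

  margin <- max_w + 20L
  min_gap <- max_w + 10L
  placed <- tibble::tibble(chrom = character(), start = integer(),
                           end = integer())
  regions <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    w <- sample(seq(config$peak_width[1], config$peak_width[2]), 1)
    ok <- FALSE
    for (try in seq_len(1000)) {
      chr <- sample(chrom_names, 1)
      lo <- margin
      hi <- config$chrom_length - w - margin
      if (hi <= lo) break
      s <- sample(seq(lo, hi), 1)
      same <- placed[placed$chrom == chr, , drop = FALSE]
      if (nrow(same) == 0 ||
          all(s >= same$end + min_gap | (s + w) <= same$start - min_gap)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not place region ", plan[[i]]$name,
           " without overlap; use longer or more chromosomes", call. = FALSE)
    }
    placed <- dplyr::bind_rows(placed,
                               tibble::tibble(chrom = chr, start = s,
                                              end = s + w))
    regions[[i]] <- c(plan[[i]],
                      list(chrom = chr, start = as.integer(s),
                           end = as.integer(s + w)))
  }

  for (i in seq_along(regions)) {
    reg <- regions[[i]]
    res <- realize_region(seqs[[reg$chrom]], reg, pwms, config$scan_fraction)
    seqs[[reg$chrom]] <- res$seq
    regions[[i]]$planted <- res$planted
  }

  genome <- vapply(seqs, paste, character(1), collapse = "")

  region_tbl <- dplyr::bind_rows(lapply(regions, function(r) {
    tibble::tibble(chrom = r$chrom, start = r$start, end = r$end,
                   name = r$name, fails = paste(r$fails, collapse = ","),
                   straddle = r$straddle)
  }))
  region_tbl <- region_tbl[order(region_tbl$chrom, region_tbl$start,
                                 method = "radix"), , drop = FALSE]

  peak_tbl <- function(source) {
    keep <- !vapply(strsplit(region_tbl$fails, ",", fixed = TRUE),
                    function(f) source %in% f, logical(1))
    x <- region_tbl[keep, c("chrom", "start", "end", "name"), drop = FALSE]
    if (source != "dll_chip" && config$peak_jitter > 0 && nrow(x) > 0) {
      x$start <- pmax(0L, x$start -
                        sample(0:config$peak_jitter, nrow(x), replace = TRUE))
      x$end <- pmin(config$chrom_length, x$end +
                      sample(0:config$peak_jitter, nrow(x), replace = TRUE))
    }
    x$score <- NA_real_
    x$strand <- "."
    x$source <- source
    x
  }
  peaks <- list(dll_chip = peak_tbl("dll_chip"),
                sp1_chip = peak_tbl("sp1_chip"),
                faire = peak_tbl("faire"))

  transcripts <- local({
    n <- config$n_transcripts
    if (n == 0) {
      return(tibble::tibble(chrom = character(), start = integer(),
                            end = integer(), transcript_id = character(),
                            gene_id = character(), strand = character()))
    }
    chr <- chrom_names[((seq_len(n) - 1L) %% config$n_chroms) + 1L]
    w <- sample(500:2000, n, replace = TRUE)
    s <- vapply(w, function(wi) {
      sample(seq(0L, config$chrom_length - wi), 1)
    }, numeric(1))
    gene <- sprintf("gene%03d", seq_len(n))
    out <- tibble::tibble(chrom = chr, start = as.integer(s),
                          end = as.integer(s + w),
                          transcript_id = paste0(gene, ".t1"),
                          gene_id = gene,
                          strand = sample(c("+", "-"), n, replace = TRUE))
    out[order(out$chrom, out$start, method = "radix"), , drop = FALSE]
  })

  is_true <- !nzchar(region_tbl$fails)
  true_crms <- region_tbl[is_true, c("chrom", "start", "end", "name"),
                          drop = FALSE]
  decoys <- region_tbl[!is_true, , drop = FALSE]
  planted_hits <- dplyr::bind_rows(lapply(regions, function(r) {
    if (length(r$planted) == 0) return(NULL)
    dplyr::bind_rows(lapply(names(r$planted), function(cls) {
      tibble::tibble(chrom = r$chrom, start = r$planted[[cls]][1],
                     end = r$planted[[cls]][2], class = cls, strand = "+",
                     region = r$name)
    }))
  }))
  tx_assign <- if (nrow(true_crms) > 0 && nrow(transcripts) > 0) {
    # construction-level brute force (same tie-break the contract states)
    dplyr::bind_rows(lapply(seq_len(nrow(true_crms)), function(i) {
      ti <- which(transcripts$chrom == true_crms$chrom[i])
      if (length(ti) == 0) {
        return(tibble::tibble(region = true_crms$name[i],
                              gene_id = NA_character_,
                              transcript_id = NA_character_,
                              distance = NA_integer_))
      }
      d <- pmax(0L, pmax(true_crms$start[i], transcripts$start[ti]) -
                  pmin(true_crms$end[i], transcripts$end[ti]))
      o <- ti[order(d, transcripts$start[ti], transcripts$transcript_id[ti],
                    method = "radix")[1]]
      tibble::tibble(region = true_crms$name[i],
                     gene_id = transcripts$gene_id[o],
                     transcript_id = transcripts$transcript_id[o],
                     distance = as.integer(min(d)))
    }))
  } else {
    tibble::tibble(region = character(), gene_id = character(),
                   transcript_id = character(), distance = integer())
  }
  truth <- structure(list(true_crms = true_crms, decoys = decoys,
                          planted_hits = planted_hits,
                          transcript_assignments = tx_assign),
                     class = "synthetic_truth")

  out <- list(genome = genome, peaks = peaks, transcripts = transcripts,
              pwms = pwms, truth = truth, config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(genome = file.path(outdir, "genome.fa"))
    write_fasta(genome, paths[["genome"]])
    for (src in names(peaks)) {
      paths[[src]] <- file.path(outdir, paste0(src, ".bed"))
      write_bed(peaks[[src]], paths[[src]])
    }
    paths[["transcripts"]] <- file.path(outdir, "transcripts.bed")
    tx_bed <- tibble::tibble(chrom = transcripts$chrom,
                             start = transcripts$start,
                             end = transcripts$end,
                             name = paste0(transcripts$gene_id, "|",
                                           transcripts$transcript_id),
                             score = NA_real_,
                             strand = transcripts$strand)
    write_bed(tx_bed, paths[["transcripts"]])
    for (cls in classes) {
      paths[[paste0("pwm_", cls)]] <-
        file.path(outdir, paste0("pwm_", cls, ".txt"))
      write_pwm_jaspar(pwms[[cls]], paths[[paste0("pwm_", cls)]])
    }
    paths[["truth"]] <- file.path(outdir, "truth.tsv")
    write_truth(truth, paths[["truth"]])
    out$paths <- paths
  }
  out
}

# Fill one region with background + planted motif instances, re-drawing
# chance hits of forbidden classes until the region realises its intended
# condition pattern. Planted instances are sampled column-wise from the PWM,
# so at sharpness 1.0 they are the exact consensus and the region's
# recoverability is guaranteed, while at lower sharpness instances may fall
# below the scan threshold (the basis of the graded-degradation behaviour).
# Decoy regions must realise their pattern exactly — every non-failed motif
# class above threshold, every failed class absent — and are retried until
# they do. `chrom_seq` is the chromosome as a character vector; returns the
# updated vector plus the planted instance spans.
realize_region <- function(chrom_seq, reg, pwms, scan_fraction) {
  classes <- names(pwms)
  fail_motifs <- intersect(reg$fails, classes)
  plant_inside <- setdiff(classes, fail_motifs)
  forbidden <- fail_motifs
  if (reg$straddle) forbidden <- union(forbidden, "dll")
  is_decoy <- length(reg$fails) > 0 || reg$straddle
  gc <- mean(chrom_seq %in% c("G", "C"))
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  span_lo <- reg$start + 1L          # 1-based
  span_hi <- reg$end + if (reg$straddle) 1L else 0L

  for (outer in seq_len(40)) {
    work <- chrom_seq
    work[span_lo:span_hi] <- sample(c("A", "C", "G", "T"),
                                    span_hi - span_lo + 1L, replace = TRUE,
                                    prob = prob)
    planted <- list()
    spans <- matrix(integer(0), ncol = 2)   # 0-based half-open
    ok <- TRUE
    for (cls in plant_inside) {
      W <- pwms[[cls]]$width
      placed_ok <- FALSE
      for (try in seq_len(100)) {
        s <- sample(seq(reg$start + 2L, reg$end - W - 2L), 1)
        if (nrow(spans) == 0 ||
            all(s >= spans[, 2] + 1L | (s + W) <= spans[, 1] - 1L)) {
          placed_ok <- TRUE
          break
        }
      }
      if (!placed_ok) {
        ok <- FALSE
        break
      }
      work[(s + 1L):(s + W)] <- sample_instance(pwms[[cls]])
      spans <- rbind(spans, c(s, s + W))
      planted[[cls]] <- c(s, s + W)
    }
    if (!ok) next
    straddle_seq <- NULL
    if (reg$straddle) {
      W <- pwms[["dll"]]$width
      s <- reg$end - W + 1L           # overlaps the peak by W-1, exits by 1
      straddle_seq <- sample_instance(pwms[["dll"]])
      work[(s + 1L):(s + W)] <- straddle_seq
      spans <- rbind(spans, c(s, s + W))
      planted[["dll"]] <- c(s, s + W)
    }

    # scrub chance hits of forbidden classes that fall fully inside the peak
    clean <- length(forbidden) == 0
    if (!clean) {
      for (round in seq_len(25)) {
        sub <- paste(work[(reg$start + 1L):reg$end], collapse = "")
        bad <- dplyr::bind_rows(lapply(forbidden, function(cls) {
          scan_sequence(stats::setNames(sub, "sub"), pwms[[cls]],
                        scan_fraction, strands = "both")
        }))
        if (nrow(bad) == 0) {
          clean <- TRUE
          break
        }
        overlap_plant <- vapply(seq_len(nrow(bad)), function(k) {
          hs <- reg$start + bad$start[k]
          he <- reg$start + bad$end[k]
          nrow(spans) > 0 && any(hs < spans[, 2] & spans[, 1] < he)
        }, logical(1))
        if (any(overlap_plant)) break   # cannot scrub without harming a plant
        for (k in seq_len(nrow(bad))) {
          hs <- reg$start + bad$start[k]
          he <- reg$start + bad$end[k]
          work[(hs + 1L):he] <- sample(c("A", "C", "G", "T"), he - hs,
                                       replace = TRUE, prob = prob)
        }
      }
    }
    if (!clean) next

    if (is_decoy) {
      # a decoy's non-failed motif conditions must hold above threshold
      sub <- paste(work[(reg$start + 1L):reg$end], collapse = "")
      have <- vapply(plant_inside, function(cls) {
        nrow(scan_sequence(stats::setNames(sub, "sub"), pwms[[cls]],
                           scan_fraction, strands = "both")) > 0
      }, logical(1))
      if (!all(have)) next
      if (reg$straddle) {
        thr <- threshold_from_fraction(pwms[["dll"]], scan_fraction)
        sc <- window_score(pwms[["dll"]], paste(straddle_seq, collapse = ""))
        if (is.na(sc) || sc < thr - 1e-9) next
      }
    }

    planted <- lapply(planted, function(p) as.integer(p))
    return(list(seq = work, planted = planted))
  }
  stop("could not realise region ", reg$name, " within the retry budget; ",
       "use longer chromosomes or fewer regions", call. = FALSE)
}

# draw one instance column-wise from the PWM probabilities; at sharpness 1.0
# this is the exact consensus
sample_instance <- function(p) {
  vapply(seq_len(p$width), function(j) {
    sample(c("A", "C", "G", "T"), 1, prob = p$matrix[, j])
  }, character(1))
}

consensus_of <- function(p) {
  paste(c("A", "C", "G", "T")[apply(p$matrix, 2, which.max)], collapse = "")
}

#' Serialise a synthetic ground-truth ledger to TSV
#'
#' One documented TSV holds all four record types, distinguished by the
#' `record` column: `true_crm` (planted CRM intervals and names), `decoy`
#' (intervals plus the comma-joined failed conditions and the straddle
#' flag), `planted_hit` (exact motif instances written into the sequence,
#' with class and region), and `transcript_assignment` (intended nearest
#' gene per true CRM). Unused fields hold `'.'`.
#'
#' @param truth A `synthetic_truth` object from [simulate_crm_data()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cols <- c("record", "chrom", "start", "end", "name", "fails", "straddle",
            "class", "strand", "region", "gene_id", "transcript_id",
            "distance")
  blank <- function(n) rep(".", n)
  rows <- list(
    data.frame(record = rep("true_crm", nrow(truth$true_crms)),
               chrom = truth$true_crms$chrom, start = truth$true_crms$start,
               end = truth$true_crms$end, name = truth$true_crms$name,
               fails = blank(nrow(truth$true_crms)),
               straddle = blank(nrow(truth$true_crms)),
               class = blank(nrow(truth$true_crms)),
               strand = blank(nrow(truth$true_crms)),
               region = blank(nrow(truth$true_crms)),
               gene_id = blank(nrow(truth$true_crms)),
               transcript_id = blank(nrow(truth$true_crms)),
               distance = blank(nrow(truth$true_crms))),
    data.frame(record = rep("decoy", nrow(truth$decoys)),
               chrom = truth$decoys$chrom, start = truth$decoys$start,
               end = truth$decoys$end, name = truth$decoys$name,
               fails = truth$decoys$fails,
               straddle = tolower(as.character(truth$decoys$straddle)),
               class = blank(nrow(truth$decoys)),
               strand = blank(nrow(truth$decoys)),
               region = blank(nrow(truth$decoys)),
               gene_id = blank(nrow(truth$decoys)),
               transcript_id = blank(nrow(truth$decoys)),
               distance = blank(nrow(truth$decoys))),
    data.frame(record = rep("planted_hit", nrow(truth$planted_hits)),
               chrom = truth$planted_hits$chrom,
               start = truth$planted_hits$start,
               end = truth$planted_hits$end,
               name = blank(nrow(truth$planted_hits)),
               fails = blank(nrow(truth$planted_hits)),
               straddle = blank(nrow(truth$planted_hits)),
               class = truth$planted_hits$class,
               strand = truth$planted_hits$strand,
               region = truth$planted_hits$region,
               gene_id = blank(nrow(truth$planted_hits)),
               transcript_id = blank(nrow(truth$planted_hits)),
               distance = blank(nrow(truth$planted_hits))),
    data.frame(record = rep("transcript_assignment",
                            nrow(truth$transcript_assignments)),
               chrom = blank(nrow(truth$transcript_assignments)),
               start = blank(nrow(truth$transcript_assignments)),
               end = blank(nrow(truth$transcript_assignments)),
               name = blank(nrow(truth$transcript_assignments)),
               fails = blank(nrow(truth$transcript_assignments)),
               straddle = blank(nrow(truth$transcript_assignments)),
               class = blank(nrow(truth$transcript_assignments)),
               strand = blank(nrow(truth$transcript_assignments)),
               region = truth$transcript_assignments$region,
               gene_id = truth$transcript_assignments$gene_id,
               transcript_id = truth$transcript_assignments$transcript_id,
               distance = truth$transcript_assignments$distance)
  )
  all <- do.call(rbind, rows)[, cols]
  utils::write.table(all, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Read a synthetic ground-truth ledger
#'
#' @param path TSV written by [write_truth()].
#' @return A `synthetic_truth` object.
#' @export
read_truth <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = "character", na.strings = character(0))
  pick <- function(rec) x[x$record == rec, , drop = FALSE]
  tc <- pick("true_crm")
  dc <- pick("decoy")
  ph <- pick("planted_hit")
  ta <- pick("transcript_assignment")
  structure(list(
    true_crms = tibble::tibble(chrom = tc$chrom,
                               start = as.integer(tc$start),
                               end = as.integer(tc$end), name = tc$name),
    decoys = tibble::tibble(chrom = dc$chrom, start = as.integer(dc$start),
                            end = as.integer(dc$end), name = dc$name,
                            fails = dc$fails,
                            straddle = dc$straddle == "true"),
    planted_hits = tibble::tibble(chrom = ph$chrom,
                                  start = as.integer(ph$start),
                                  end = as.integer(ph$end),
                                  class = ph$class, strand = ph$strand,
                                  region = ph$region),
    transcript_assignments = tibble::tibble(
      region = ta$region, gene_id = ta$gene_id,
      transcript_id = ta$transcript_id,
      distance = suppressWarnings(as.integer(ta$distance)))
  ), class = "synthetic_truth")
}

#' Score predicted candidates against the planted truth
#'
#' Matching is by interval identity (`chrom`, `start`, `end`) against the
#' truth's anchor-peak coordinates. Precision is defined as 1 when there are
#' no predictions, recall as 1 when there is no truth.
#'
#' @param predicted Interval table of predicted candidates (e.g. the output
#'   of [run_crm_pipeline()] or a BED read back with [read_bed()]).
#' @param truth A `synthetic_truth` object.
#' @return A list with integer `true_positives`, `false_positives`,
#'   `false_negatives` and numeric `precision`, `recall`.
#' @export
evaluate_recovery <- function(predicted, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  validate_intervals(predicted, "predicted")
  pk <- unique(interval_key(predicted))
  tk <- unique(interval_key(truth$true_crms))
  tp <- length(intersect(pk, tk))
  fp <- length(setdiff(pk, tk))
  fn <- length(setdiff(tk, pk))
  list(true_positives = tp, false_positives = fp, false_negatives = fn,
       precision = if (tp + fp == 0) 1 else tp / (tp + fp),
       recall = if (tp + fn == 0) 1 else tp / (tp + fn))
}
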