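# A hand-built micro-genome with three anchor peaks whose evidence patterns
# are known by construction:
#   peak1 [20,80)    all four motifs, Sp1 + FAIRE overlap  -> full candidate
#   peak2 [100,160)  all four motifs, FAIRE but no Sp1 peak
#   peak3 [200,260)  dll/pan/mad motifs (no sp1 motif), Sp1 + FAIRE overlap
micro_fixture <- function() {
  cons <- c(dll = "TTAACC", sp1 = "GGGGGG", pan = "CATCAT", mad = "GCGCGC")
  pwms <- lapply(names(cons), function(cls) {
    crmscan:::consensus_pwm(cons[[cls]], 1.0, paste0("m_", cls), cls)
  })
  filler <- function(n) strrep("AT", ceiling(n / 2))
  place <- function(motifs) paste0(paste(motifs, collapse = "ATAT"))
  seq <- paste0(filler(20),
                place(cons[c("dll", "sp1", "pan", "mad")]))      # 20..56
  seq <- paste0(seq, filler(100 - nchar(seq)))
  seq <- substr(seq, 1, 100)
  seq <- paste0(seq, place(cons[c("dll", "sp1", "pan", "mad")]))
  seq <- paste0(seq, filler(200 - nchar(seq)))
  seq <- substr(seq, 1, 200)
  seq <- paste0(seq, place(cons[c("dll", "pan", "mad")]))
  seq <- paste0(seq, filler(300 - nchar(seq)))
  genome <- c(chr1 = toupper(substr(seq, 1, 300)))
  peaks <- list(
    dll_chip = genomic_interval(rep("chr1", 3), c(20, 100, 200),
                                c(80, 160, 260),
                                name = c("peak1", "peak2", "peak3")),
    sp1_chip = genomic_interval(rep("chr1", 2), c(20, 200), c(80, 260)),
    faire = genomic_interval("chr1", 0, 300)
  )
  transcripts <- tibble::tibble(chrom = "chr1", start = 0L, end = 10L,
                                transcript_id = "g1.t1", gene_id = "g1",
                                strand = "+")
  list(genome = genome, peaks = peaks, pwms = pwms,
       transcripts = transcripts)
}

test_that("full logic keeps exactly the peaks satisfying all criteria", {
  fx <- micro_fixture()
  full <- run_full_logic(fx$genome, fx$peaks, fx$pwms, fx$transcripts,
                         verbose = FALSE)
  expect_identical(full$name, "peak1")
  expect_identical(full$start, 20L)
  # evidence counts cover every required class
  expect_true(all(c(full$n_dll, full$n_sp1, full$n_pan, full$n_mad) >= 1))
  expect_true(full$has_sp1_chip && full$has_faire)
  expect_identical(full$gene_id, "g1")
  expect_identical(full$distance, 10L)

  relaxed <- run_relaxed_logic(fx$genome, fx$peaks, fx$pwms, fx$transcripts,
                               verbose = FALSE)
  # peak2 fails only the Sp1-peak overlap, peak3 only the Sp1 motif:
  # both re-admitted once Sp1 is excluded as a factor
  expect_setequal(relaxed$name, c("peak1", "peak2", "peak3"))
  expect_true(all(interval_key(full) %in% interval_key(relaxed)))
})

test_that("candidate set equals the per-peak condition oracle on synthetic
           data", {
  for (seed in c(31, 32)) {
    sim <- simulate_crm_data(small_sim_config(seed))
    hits <- scan_pwms(sim$genome, sim$pwms, 0.8, "both")
    anchor <- sim$peaks$dll_chip
    conds <- t(vapply(seq_len(nrow(anchor)), function(i) {
      oracle_conditions(anchor[i, ], sim$peaks, hits,
                        c("dll", "sp1", "pan", "mad"))
    }, setNames(logical(7), c("dll_chip", "sp1_chip", "faire",
                              "dll", "sp1", "pan", "mad"))))
    full <- run_full_logic(sim$genome, sim$peaks, sim$pwms, sim$transcripts,
                           motif_hits = hits, verbose = FALSE)
    relaxed <- run_relaxed_logic(sim$genome, sim$peaks, sim$pwms,
                                 sim$transcripts, motif_hits = hits,
                                 verbose = FALSE)
    exp_full <- anchor[rowSums(conds) == 7, ]
    exp_rel <- anchor[conds[, "faire"] & conds[, "dll"] & conds[, "pan"] &
                        conds[, "mad"], ]
    expect_setequal(interval_key(full), interval_key(exp_full))
    expect_setequal(interval_key(relaxed), interval_key(exp_rel))
    # the relaxed-only candidates fail only Sp1-involving conditions
    only_rel <- setdiff(interval_key(exp_rel), interval_key(exp_full))
    failing <- conds[match(only_rel, interval_key(anchor)), , drop = FALSE]
    expect_true(all(failing[, c("dll_chip", "faire", "dll", "pan", "mad")]))
  }
})

test_that("motif-requirement order does not change the candidate set", {
  sim <- simulate_crm_data(small_sim_config(33))
  hits <- scan_pwms(sim$genome, sim$pwms, 0.8, "both")
  orders <- list(c("dll", "sp1", "pan", "mad"), c("mad", "pan", "sp1", "dll"),
                 c("sp1", "mad", "dll", "pan"))
  keys <- lapply(orders, function(o) {
    cfg <- criteria_config(motif_requirements = setNames(rep(1, 4), o))
    interval_key(run_crm_pipeline(sim$genome, sim$peaks, sim$pwms,
                                  sim$transcripts, cfg, motif_hits = hits,
                                  verbose = FALSE))
  })
  expect_identical(keys[[2]], keys[[1]])
  expect_identical(keys[[3]], keys[[1]])
})

test_that("candidate coordinates appear verbatim in the anchor peak table", {
  sim <- simulate_crm_data(small_sim_config(34))
  full <- run_full_logic(sim$genome, sim$peaks, sim$pwms, sim$transcripts,
                         verbose = FALSE)
  expect_true(all(interval_key(full) %in%
                    interval_key(sim$peaks$dll_chip)))
  # anchored on sp1_chip instead: coordinates come from that file
  cfg <- criteria_config(anchor = "sp1_chip",
                         peak_requirements = c(dll_chip = 1e-9,
                                               faire = 1e-9))
  alt <- run_crm_pipeline(sim$genome, sim$peaks, sim$pwms, sim$transcripts,
                          cfg, verbose = FALSE)
  expect_true(all(interval_key(alt) %in%
                    interval_key(sim$peaks$sp1_chip)))
})

test_that("missing inputs are reported by name", {
  fx <- micro_fixture()
  expect_error(run_full_logic(fx$genome, fx$peaks[c("dll_chip", "faire")],
                              fx$pwms, fx$transcripts, verbose = FALSE),
               "sp1_chip")
  expect_error(run_full_logic(fx$genome, fx$peaks, fx$pwms[1:3],
                              fx$transcripts, verbose = FALSE), "mad")
  expect_error(run_full_logic(fx$genome, fx$peaks, fx$pwms, NULL,
                              verbose = FALSE), "transcripts")
  expect_error(criteria_config(anchor = "faire"), "anchor")
  expect_error(criteria_config(motif_requirements = character(0)),
               "at least one")
})

test_that("write_report emits a lossless TSV, companion BED and metadata", {
  fx <- micro_fixture()
  full <- run_full_logic(fx$genome, fx$peaks, fx$pwms, fx$transcripts,
                         verbose = FALSE)
  prefix <- file.path(withr::local_tempdir(), "run")
  paths <- write_report(full, prefix, config = criteria_config(),
                        input_counts = c(dll_chip = 3L))
  tsv <- read.delim(paths[["tsv"]], na.strings = ".")
  expect_identical(names(tsv)[1:6],
                   c("chrom", "start", "end", "gene_id", "transcript_id",
                     "distance"))
  expect_identical(tsv$start, full$start)
  expect_identical(tsv$gene_id, full$gene_id)
  expect_identical(tsv$n_dll, full$n_dll)
  expect_identical(tsv$has_sp1_chip, full$has_sp1_chip)
  bed <- read_bed(paths[["bed"]])
  expect_identical(bed$start, full$start)
  expect_true(any(grepl("min_score_fraction: 0.8",
                        readLines(paths[["meta"]]))))

  # zero candidates: header-only TSV, empty BED
  empty <- full[0, ]
  paths0 <- write_report(empty, file.path(withr::local_tempdir(), "none"))
  expect_identical(nrow(read.delim(paths0[["tsv"]])), 0L)
  expect_identical(readLines(paths0[["bed"]]), character(0))
})

test_that("identical inputs produce byte-identical reports", {
  sim <- simulate_crm_data(small_sim_config(35))
  dir <- withr::local_tempdir()
  md5 <- character(0)
  for (run in 1:2) {
    cand <- run_full_logic(sim$genome, sim$peaks, sim$pwms, sim$transcripts,
                           verbose = FALSE)
    prefix <- file.path(dir, paste0("run", run))
    paths <- write_report(cand, prefix, config = criteria_config())
    md5 <- rbind(md5, unname(tools::md5sum(paths)))
  }
  expect_identical(md5[1, ], md5[2, ])
})
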