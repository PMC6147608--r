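---
title: "Methods: combinatorial CRM prediction and its synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combinatorial CRM prediction and its synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmscan)
```

## The model

`crmscan` predicts candidate cis-regulatory modules (CRMs) by requiring the
co-occurrence, at one genomic locus, of three kinds of evidence gathered in
*Drosophila* third-instar leg imaginal discs (or any analogous system):

* **in vivo binding** of two transcription factors, Dll and Sp1, as ChIP-seq
  peak sets;
* **chromatin accessibility**, as FAIRE-seq peaks;
* **sequence potential**, as position-weight-matrix (PWM) hits for four
  factor classes: Dll, Sp1, Pan (the nuclear effector of Wg signalling) and
  Mad (the nuclear effector of Dpp signalling).

One peak set — the Dll ChIP peaks by default — is the *anchor*: its
coordinates are what the pipeline reports. An anchor peak becomes a
candidate iff it (a) overlaps every required peak set, (b) fully contains at
least one scanning hit of every required motif class, and (c) is then
annotated with its nearest transcript. Running with all seven conditions
(anchor membership, two peak overlaps, four motif classes) is the *full
logic*; removing both Sp1 conditions gives the *relaxed logic*, whose
candidate set is provably a superset on the same inputs.

The seven conditions are implemented as independent toggles
(`criteria_config()`), so either reading of "excluding Sp1 as a factor" —
dropping only the motif, or the motif and the peak requirement — is
expressible; the default relaxed logic drops both.

## Scanning

A window of width $W$ is scored against a $4 \times W$ probability matrix
$M$ as $S = \sum_j M[x_j, j]$, i.e. probability sums rather than log-odds,
matching the semantics of scanning database probability matrices directly. A
hit is retained when $S \ge f \cdot S_{\max}$ with
$S_{\max} = \sum_j \max_b M[b,j]$.

Tunable parameters, defaults, and why:

* `min_score_fraction` ($f$), default **0.80** — the retention rule of the
  original genome scan ("minimum score of 80%"). The percent-of-maximum
  convention is the default because that is what the cited scanner computes
  on probability matrices; the min–max range convention
  ($S_{\min} + f(S_{\max}-S_{\min})$) is available via
  `convention = "range"` for sensitivity analysis. The two coincide at
  $f = 1$ and whenever $S_{\min} = 0$.
* `strands`, default **both** — the original analysis does not state whether
  the reverse strand was scanned; genome-wide motif scans conventionally
  cover both. `forward` mode exists to probe the alternative reading, and
  candidate counts under either mode should not be attributed to the source
  analysis.
* **N handling** — windows containing `N` are disqualified outright rather
  than partially scored, avoiding threshold-dependent artifacts at assembly
  gaps.
* Overlapping and abutting hits are all reported; the downstream peak-level
  "unique" step makes hit multiplicity immaterial to candidate membership.

Minus-strand scanning scores the reverse complement of each forward window
(implemented as scanning with the column-reversed, base-complemented
matrix), so all hit coordinates stay on the forward strand.

## Interval semantics

All coordinates are 0-based half-open (BED-native); GTF input is converted
on read. `intersect_report_a(a, b, min_b_fraction)` reproduces
`intersectBed -wa -u` with `-F`: an A interval is reported once, with
unchanged coordinates, iff some B feature overlaps it by at least
`min_b_fraction × length(B)` bp. Consequences worth stating:

* `min_b_fraction = 1.0` is full containment of the B feature; a B feature
  exactly coextensive with an A interval counts as contained (overlap equals
  its length).
* a tiny positive fraction (`1e-9`) reproduces plain ≥ 1 bp overlap, since
  overlaps are integral.
* strand is ignored throughout; the source intersections are
  coordinate-only.
* a comparison of floats against `fraction × length` uses a `1e-9` slack so
  that exact containment is never lost to representation error.

Peak-vs-peak steps default to ≥ 1 bp overlap and motif steps to full
containment. Requiring one whole peak inside another would be an
implausibly strict reading of the published option string, which is stated
once for the whole intersection chain; both settings are per-step
configurable so either reading can be run.

Nearest-transcript distance is unsigned (0 when overlapping, else the gap
between closest edges). Ties break to the smaller transcript start, then the
lexicographically smaller `transcript_id` — a documented, deterministic rule
rather than an arbitrary one, since annotation functions in common use do
not specify their tie behaviour. The transcript's strand is carried in the
output so users can derive orientation. Chromosome naming is literal; a
mismatch between the chromosome universes of inputs is a hard error listing
the orphans, because silently empty intersections are the classic failure
mode of BED pipelines.

## The synthetic benchmark

`simulate_crm_data()` generates, from one integer seed, a corpus emulating
the structure of the real inputs: an i.i.d. background genome at
configurable GC, three peak files, four PWMs, a transcript map, and a
ground-truth ledger. Defaults (chosen once as desk-scale realistic, not
tuned):

* 3 chromosomes × 50 kb — large enough to place ~24 regions with generous
  gaps, small enough to scan in well under a second;
* GC 0.41 — a *D. melanogaster*-like base composition;
* peak widths 200–400 bp — typical ChIP peak calls;
* consensus widths 8–10 bp with sharpness 0.9 (probability mass on the
  consensus base per column) — in the range of fly PWMs for these factor
  families; widths ≥ 8 keep chance hits at the 0.80 threshold rare enough
  that decoys can be made clean;
* 10 true CRMs, 2 decoys per failure pattern, 30 transcripts.

True CRMs are intervals present identically in all three peak files (an
optional jitter widens the non-anchor copies) into which one instance per
motif class is written, *sampled column-wise from the class PWM*: at
sharpness 1.0 this is the exact consensus and recovery is guaranteed; at
lower sharpness instances can fall below the scan threshold, which is the
designed mechanism behind the graded-degradation property (mean recall is
non-increasing in sharpness across seeds — per-seed monotonicity is not
guaranteed because instances are random draws).

Decoys realise single-condition failure patterns: absence from the Sp1 or
FAIRE peak file, or absence of one motif class's contained hits. Because
chance hits at 80% of maximum do occur in random background, the generator
scans each decoy and re-draws offending windows (or, if a chance hit
overlaps a planted instance, the whole region) until the intended pattern
holds exactly; decoys likewise retry until all their *non*-failed motif
conditions hold above threshold. The special `straddle_dll` pattern plants
the Dll instance overhanging the peak's right edge by exactly 1 bp — fully
present in the genome, never fully contained in the peak — to probe the
containment boundary: rejected at `min_b_fraction = 1.0`, admitted in
≥ 1 bp mode.

What the generator does **not** emulate: Markovian or isochore base
composition, ChIP fragment pileups and peak-caller noise, summit-position
information, motif clustering biology, or dm3's real sequence. A green
recovery test therefore establishes that the pipeline's *logic and interval
semantics* are correct, not that the thresholds are well-calibrated for real
chromatin — and the source study's candidate counts (hundreds of loci under
the full logic, thousands without Sp1) are deliberately not reproduction
targets, as they depend on externally processed alignment and peak-calling
products.

Determinism: one global seed drives a single RNG stream; writers use fixed
field formatting (integer scores without decimals, fractional scores with
four), so identical configs give byte-identical corpora and reports. The
truth ledger serialises to a single documented TSV (`write_truth()`) so
evaluations can be re-run without regeneration.

## Numerical and degenerate-input choices

* PWM columns are count-normalised unless they already sum to 1 within
  1e-6; all-zero or negative columns are format errors.
* `evaluate_recovery` defines precision = 1 with no predictions and
  recall = 1 with no truth (empty-set conventions).
* A PWM wider than every chromosome yields an empty hit set with a warning,
  not an error; a `>`-only FASTA record is a zero-length chromosome with a
  warning.
* narrowPeak summit `-1` means "absent" (ENCODE convention); summits outside
  the peak are format errors.
* Multiple PWMs of one factor class are OR-combined: any full hit from any
  matrix of the class satisfies the class requirement.
* The report's metadata block echoes the configuration, package version and
  input record counts; it intentionally omits timestamps and file digests so
  reports stay byte-reproducible.

## Known limitations

* The scanner is exact and exhaustive, not heuristic; it is sized for
  desk-scale genomes (tens of Mb are fine; a whole mammalian genome would
  want a compiled scanner).
* Motif score p-values, higher-order background models and motif discovery
  are out of scope.
* Peak calling is upstream: peaks are consumed as called, and the published
  significance cutoffs apply to that upstream step, not here.
* `nearest_transcript` treats transcripts as opaque intervals; promoter- or
  TSS-relative distances are derivable from the reported strand but not
  built in.
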