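#' Default simulation configuration
#'
#' One self-contained study design at desk scale: three synthetic seed EVEs
#' (1.5 kb, labeled synthetic — they stand in for real seed elements, which
#' live in external databases), a 50-kb repeat-rich genome, three planted
#' integrations (a full element with multicopy siRNA-flagged flanks, a
#' 5'-truncated element, and a two-element fusion), 2 x 151 paired-end DNA
#' reads at ~30x, and a 10,000-read small-RNA library under the
#' primary-piRNA model.
#'
#' @param seed master seed; sub-generators use fixed offsets from it.
#' @param genome_length genome length (bp).
#' @param dna_coverage target DNA coverage (x).
#' @param n_small_rna small-RNA reads.
#' @return A nested configuration list.
#' @export
simulate_config <- function(seed = 1L, genome_length = 50000L,
                            dna_coverage = 30, n_small_rna = 10000L) {
  seed <- as.integer(seed) %% 1000000L
  list(seed = seed,
       genome = genome_spec(length = genome_length, seed = seed),
       eve_len = 1500L, n_eves = 3L,
       plans = list(
         integration_plan("EVE1", "full", flank_copy_number = 5L,
                          sirna = TRUE),
         integration_plan("EVE2", "five_prime_truncated",
                          truncation_len = 200L),
         integration_plan("EVE3", "fusion", partner_eve_id = "EVE2",
                          strand = "-")),
       dna_coverage = dna_coverage,
       n_small_rna = as.integer(n_small_rna))
}

#' Simulate a full study data set and write it to disk
#'
#' Writes the seed EVE FASTA, the integrated genome FASTA, the integration
#' truth (BED + JSON sidecar), the paired DNA FASTQ files, the small-RNA
#' FASTQ, and a manifest JSON with seeds, read counts and md5 checksums.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [simulate_config] list.
#' @return Invisibly, a list with the in-memory objects (`eves`, `genome`,
#'   `truth`, `dna`, `smallrna`) and the `manifest`.
#' @export
run_simulate <- function(out_dir, config = simulate_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  seed <- config$seed
  eves <- with_seed(seed + 1L, seq_records(
    paste0("EVE", seq_len(config$n_eves)),
    vapply(seq_len(config$n_eves), function(i) random_seq(config$eve_len, 0.5),
           character(1))))
  base <- make_repeat_rich_genome(config$genome)
  ig <- integrate_eves(base, eves, config$plans, seed = seed + 2L)
  glen <- nchar(ig$genome$seq[1])
  n_pairs <- ceiling(config$dna_coverage * glen / 302)
  dna <- simulate_dna_reads(ig$genome,
                            dna_read_model(n_pairs = n_pairs,
                                           seed = seed + 3L))
  sr <- simulate_small_rna(ig, ig$truth,
                           small_rna_model(n_reads = config$n_small_rna,
                                           seed = seed + 4L))
  f <- function(x) file.path(out_dir, x)
  write_fasta(eves, f("eves.fasta"))
  write_fasta(ig$genome, f("genome.fasta"))
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", ig$truth$contig,
                     ig$truth$start, ig$truth$end, ig$truth$eve_id,
                     ig$truth$strand), f("truth.bed"))
  jsonlite::write_json(.truth_json(ig$truth), f("truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_fastq(dna$r1, f("dna_R1.fastq"))
  write_fastq(dna$r2, f("dna_R2.fastq"))
  write_fastq(sr, f("smallrna.fastq"))
  files <- c("eves.fasta", "genome.fasta", "truth.bed", "truth.json",
             "dna_R1.fastq", "dna_R2.fastq", "smallrna.fastq")
  manifest <- list(
    seed = seed,
    sub_seeds = list(eves = seed + 1L, integration = seed + 2L,
                     dna = seed + 3L, smallrna = seed + 4L),
    genome_length = glen, n_dna_pairs = nrow(dna$r1),
    n_small_rna = nrow(sr),
    checksums = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(eves = eves, genome = ig$genome, truth = ig$truth,
                 dna = dna, smallrna = sr, manifest = manifest))
}

.truth_json <- function(truth) {
  lapply(seq_len(nrow(truth)), function(i) list(
    eve_id = truth$eve_id[i], contig = truth$contig[i],
    start = truth$start[i], end = truth$end[i], strand = truth$strand[i],
    mode = truth$mode[i], flank_copy_number = truth$flank_copy_number[i],
    sirna = truth$sirna[i],
    flank_intervals = truth$flank_intervals[[i]],
    segments = truth$segments[[i]]))
}

.read_reads_arg <- function(reads_fastq) {
  reads <- lapply(reads_fastq, read_fastq)
  if (length(reads) == 2L) list(r1 = reads[[1]], r2 = reads[[2]])
  else reads[[1]]
}

#' Run the discovery screen from files
#'
#' Reads seed EVEs (FASTA) and DNA reads (one or two FASTQ files), runs
#' [iterative_screen] and [call_presence], and writes: contigs FASTA
#' (headers annotated with length/depth/reads), a segment table TSV, a
#' presence matrix TSV (elements x sample, cells `+` / `partial` / `-`),
#' and a per-iteration JSON-lines log.
#'
#' @param seeds_fasta path to the seed EVE FASTA.
#' @param reads_fastq character vector of one or two FASTQ paths.
#' @param out_dir output directory.
#' @param cfg a [screen_config].
#' @param sample_id sample label for the presence matrix.
#' @return Invisibly, the `eve_screen` object (with `presence` attached).
#' @export
run_screen <- function(seeds_fasta, reads_fastq, out_dir,
                       cfg = screen_config(), sample_id = "sample1") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- read_fasta(seeds_fasta)
  reads <- .read_reads_arg(reads_fastq)
  scr <- iterative_screen(seeds, reads, cfg)
  pres <- call_presence(seeds, reads, cfg, sample_id)
  f <- function(x) file.path(out_dir, x)
  write_contigs_fasta(scr$contigs, f("contigs.fasta"))
  seg <- do.call(rbind, lapply(names(scr$annotations), function(id) {
    a <- scr$annotations[[id]]
    cbind(data.frame(contig = id, stringsAsFactors = FALSE), a$segments,
          iteration = a$iteration_found)
  }))
  if (is.null(seg))
    seg <- data.frame(contig = character(), start = integer(),
                      end = integer(), label = character(),
                      strand = character(), identity = numeric(),
                      iteration = integer())
  utils::write.table(seg, f("segments.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mat <- data.frame(element = pres$element_id,
                    cell = ifelse(pres$call == "present", "+",
                                  ifelse(pres$call == "partial", "partial",
                                         "-")))
  names(mat)[2] <- sample_id
  utils::write.table(mat, f("presence.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(vapply(scr$log, function(l)
    jsonlite::toJSON(l, auto_unbox = TRUE, digits = NA), character(1)),
    f("iterations.jsonl"))
  attr(scr, "presence") <- pres
  invisible(scr)
}

#' Run small-RNA profiling from files
#'
#' Maps a small-RNA FASTQ against reference loci with at most one mismatch
#' and writes, per reference: a strand-resolved depth TSV, a size
#' distribution TSV, a positional nucleotide-frequency TSV, plus one
#' classification JSON covering all references (thresholds echoed), and
#' optionally a SAM of the placements.
#'
#' @param refs_fasta reference FASTA (element or element-plus-flank loci).
#' @param reads_fastq small-RNA FASTQ path.
#' @param out_dir output directory.
#' @param max_mismatch mismatch allowance (default 1).
#' @param length_class length class for the nucleotide-frequency matrix;
#'   `NULL` (default) uses each locus's modal length.
#' @param thresholds a [classify_thresholds].
#' @param trim optional [trim_config] applied before mapping.
#' @param write_sam also write `placements.sam`.
#' @param seed mapper tie-breaking seed.
#' @return Invisibly, a list with `placements`, `profiles`,
#'   `classifications`.
#' @export
run_smallrna <- function(refs_fasta, reads_fastq, out_dir,
                         max_mismatch = 1L, length_class = NULL,
                         thresholds = classify_thresholds(), trim = NULL,
                         write_sam = FALSE, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  refs <- read_fasta(refs_fasta)
  reads <- read_fastq(reads_fastq)
  if (!is.null(trim)) reads <- trim_reads(reads, trim)
  ok <- nchar(reads$seq) >= 15 & nchar(reads$seq) <= 40
  reads <- reads[ok, , drop = FALSE]
  pl <- if (nrow(reads)) map_small_rna(reads, refs, max_mismatch, seed)
        else .empty_placements()
  f <- function(x) file.path(out_dir, x)
  profiles <- list(); classifications <- list()
  for (rid in refs$id) {
    sub <- pl[pl$ref_id == rid, , drop = FALSE]
    prof <- small_rna_profile(sub, refs[refs$id == rid, ], length_class)
    cls <- classify_locus(prof, thresholds)
    profiles[[rid]] <- prof; classifications[[rid]] <- cls
    utils::write.table(
      data.frame(position = seq_len(prof$length) - 1L,
                 depth_fwd = prof$depth_fwd, depth_rev = prof$depth_rev),
      f(sprintf("profile_%s.tsv", rid)), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(length = 18:35, count_fwd = unname(prof$size_hist_fwd),
                 count_rev = unname(prof$size_hist_rev)),
      f(sprintf("sizes_%s.tsv", rid)), sep = "\t", quote = FALSE,
      row.names = FALSE)
    nt <- t(prof$ntfreq)
    utils::write.table(
      cbind(data.frame(position = seq_len(nrow(nt))), as.data.frame(nt)),
      f(sprintf("ntfreq_%s.tsv", rid)), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  jsonlite::write_json(lapply(classifications, unclass),
                       f("classification.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (write_sam) {
    write_sam_lite(pl, stats::setNames(nchar(refs$seq), refs$id),
                   f("placements.sam"))
  }
  invisible(list(placements = pl, profiles = profiles,
                 classifications = classifications))
}

#' Run DNA coverage analysis from files
#'
#' Maps DNA reads to each reference, writes depth TSV + bedGraph + gaps BED
#' per reference, and — when an intervals BED provides `element` / `flank`
#' rows for a reference — a multicopy call JSON.
#'
#' @param refs_fasta reference FASTA.
#' @param reads_fastq one or two FASTQ paths.
#' @param out_dir output directory.
#' @param intervals_bed optional BED path (contig, start, end, name) with
#'   names `element` or `flank`.
#' @param cfg a [screen_config] (mapping thresholds are taken from it).
#' @param ratio_threshold multicopy ratio threshold.
#' @return Invisibly, `list(profiles, calls)`.
#' @export
run_coverage <- function(refs_fasta, reads_fastq, out_dir,
                         intervals_bed = NULL, cfg = screen_config(),
                         ratio_threshold = 3.0) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  refs <- read_fasta(refs_fasta)
  reads <- .read_reads_arg(reads_fastq)
  iv <- NULL
  if (!is.null(intervals_bed)) {
    iv <- utils::read.table(intervals_bed, sep = "\t",
                            col.names = c("contig", "start", "end", "name"),
                            stringsAsFactors = FALSE)
  }
  f <- function(x) file.path(out_dir, x)
  profiles <- list(); calls <- list()
  for (rid in refs$id) {
    ref1 <- refs[refs$id == rid, ]
    pl <- map_dna_reads(reads, ref1, cfg$scoring, cfg$map_min_identity,
                        cfg$min_aligned, cfg$seed)
    prof <- depth_profile(pl, ref1)
    profiles[[rid]] <- prof
    write_depth_tracks(prof, f(sprintf("depth_%s.tsv", rid)),
                       f(sprintf("depth_%s.bedGraph", rid)),
                       f(sprintf("gaps_%s.bed", rid)))
    if (!is.null(iv)) {
      el <- iv[iv$contig == rid & iv$name == "element", , drop = FALSE]
      fl <- iv[iv$contig == rid & iv$name == "flank", , drop = FALSE]
      if (nrow(el) && nrow(fl))
        calls[[rid]] <- multicopy_call(prof, el, fl, ratio_threshold)
    }
  }
  if (length(calls))
    jsonlite::write_json(lapply(calls, unclass), f("multicopy_calls.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(profiles = profiles, calls = calls))
}

#' Consolidated per-element report
#'
#' Joins the outputs of prior commands found under `run_dir` (presence
#' matrix, multicopy calls, small-RNA classifications, contig segments)
#' into one row per element: report JSON plus a markdown table. Missing
#' inputs are listed as warnings and the report stays partial.
#'
#' @param run_dir directory holding prior command outputs.
#' @param out_dir output directory (default `run_dir`).
#' @return Invisibly, the report list.
#' @export
run_report <- function(run_dir, out_dir = run_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings <- character(0)
  g <- function(x) file.path(run_dir, x)
  pres <- NULL
  if (file.exists(g("presence.tsv"))) {
    pres <- utils::read.table(g("presence.tsv"), sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE, check.names = FALSE)
  } else warnings <- c(warnings, "missing presence.tsv")
  mc <- if (file.exists(g("multicopy_calls.json")))
    jsonlite::read_json(g("multicopy_calls.json")) else {
      warnings <- c(warnings, "missing multicopy_calls.json"); NULL
    }
  cls <- if (file.exists(g("classification.json")))
    jsonlite::read_json(g("classification.json")) else {
      warnings <- c(warnings, "missing classification.json"); NULL
    }
  seg <- if (file.exists(g("segments.tsv")))
    utils::read.table(g("segments.tsv"), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE) else {
      warnings <- c(warnings, "missing segments.tsv"); NULL
    }
  elements <- unique(c(if (!is.null(pres)) pres$element,
                       names(mc), names(cls)))
  rows <- lapply(elements, function(e) {
    contigs <- if (!is.null(seg))
      unique(seg$contig[seg$label == e]) else character(0)
    list(element = e,
         presence = if (!is.null(pres) && e %in% pres$element)
           pres[[2]][match(e, pres$element)] else NA,
         multicopy_ratio = if (!is.null(mc) && !is.null(mc[[e]]))
           mc[[e]]$ratio else NA,
         primary_pirna_like = if (!is.null(cls) && !is.null(cls[[e]]))
           cls[[e]]$primary_pirna_like else NA,
         sirna_peak = if (!is.null(cls) && !is.null(cls[[e]]))
           cls[[e]]$sirna_peak else NA,
         contigs = contigs)
  })
  report <- list(elements = rows, warnings = warnings,
                 thresholds = if (!is.null(cls) && length(cls))
                   cls[[1]]$thresholds else NULL)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  md <- c("| element | presence | multicopy ratio | piRNA-like | siRNA peak | contigs |",
          "|---|---|---|---|---|---|",
          vapply(rows, function(r) sprintf(
            "| %s | %s | %s | %s | %s | %s |", r$element,
            as.character(r$presence),
            if (is.na(r$multicopy_ratio[1])) "NA"
            else sprintf("%.2f", as.numeric(r$multicopy_ratio)),
            as.character(r$primary_pirna_like),
            as.character(r$sirna_peak),
            if (length(r$contigs)) paste(r$contigs, collapse = ",")
            else "-"), character(1)))
  if (length(warnings))
    md <- c(md, "", paste("warning:", warnings))
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(report)
}
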