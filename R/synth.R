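#' Specification of a repeat-rich synthetic host genome
#'
#' The generator emulates the salient property of culicine mosquito genomes
#' for this analysis: a large repetitive fraction (those genomes harbor
#' roughly 50--70% repeats, mostly retroelements), into which viral elements
#' integrate. Repeat copies are mutated (<= 5% divergence) instances of
#' per-family consensus sequences scattered at non-overlapping positions.
#'
#' @param length genome length in bp.
#' @param repeat_fraction target fraction of the genome covered by repeat
#'   copies (default 0.6, the middle of the 50--70% range).
#' @param repeat_unit_len repeat unit length in bp.
#' @param repeat_copy_range integer `c(min, max)` copies per family.
#' @param n_repeat_families number of repeat families.
#' @param gc GC content of background sequence and repeat consensi
#'   (default 0.4; culicine genomes are AT-rich).
#' @param seed integer seed; the generator is a pure function of the spec.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(length = 50000L, repeat_fraction = 0.6,
                        repeat_unit_len = 500L, repeat_copy_range = c(3L, 30L),
                        n_repeat_families = 20L, gc = 0.4, seed = 1L) {
  stopifnot(repeat_fraction >= 0, repeat_fraction <= 1,
            length >= repeat_unit_len, gc >= 0, gc <= 1,
            repeat_copy_range[1] >= 1,
            repeat_copy_range[2] >= repeat_copy_range[1])
  structure(list(length = as.integer(length),
                 repeat_fraction = repeat_fraction,
                 repeat_unit_len = as.integer(repeat_unit_len),
                 repeat_copy_range = as.integer(repeat_copy_range),
                 n_repeat_families = as.integer(n_repeat_families),
                 gc = gc, seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate a repeat-rich genome
#'
#' Builds an i.i.d. background sequence, then overwrites random
#' non-overlapping windows with mutated copies (uniform divergence in
#' [0, 0.05], random strand) of repeat-family consensi until the covered
#' fraction reaches `spec$repeat_fraction`. Placement first tries rejection
#' sampling and falls back to exact enumeration of free windows; if coverage
#' is unattainable within 10x the needed number of placements, an error
#' reports the achieved fraction.
#'
#' @param spec a [genome_spec].
#' @return `list(genome = seq_records, repeats = data.frame)` where `repeats`
#'   has 0-based half-open columns `start`, `end` plus `family`, `strand`.
#' @export
make_repeat_rich_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    g <- random_seq(spec$length, spec$gc)
    ann <- data.frame(start = integer(), end = integer(),
                      family = character(), strand = character(),
                      stringsAsFactors = FALSE)
    if (spec$repeat_fraction > 0) {
      fams <- vapply(seq_len(spec$n_repeat_families),
                     function(i) random_seq(spec$repeat_unit_len, spec$gc),
                     character(1))
      copies <- sample(spec$repeat_copy_range[1]:spec$repeat_copy_range[2],
                       spec$n_repeat_families, replace = TRUE)
      queue <- sample(rep.int(seq_len(spec$n_repeat_families), copies))
      occ <- logical(spec$length)
      u <- spec$repeat_unit_len
      covered <- 0L
      target <- spec$repeat_fraction * spec$length
      max_attempts <- 10L * ceiling(target / u)
      attempts <- 0L
      qi <- 0L
      while (covered < target) {
        qi <- qi + 1L
        if (qi > length(queue) || attempts >= max_attempts)
          stop(sprintf(
            "repeat_fraction %.2f unattainable: achieved %.3f after %d attempts",
            spec$repeat_fraction, covered / spec$length, attempts))
        fam <- queue[qi]
        placed <- FALSE
        for (try in 1:10) {
          attempts <- attempts + 1L
          st <- sample.int(spec$length - u + 1L, 1L)
          if (!any(occ[st:(st + u - 1L)])) { placed <- TRUE; break }
        }
        if (!placed) {
          # enumerate free windows exactly
          r <- rle(occ)
          ends <- cumsum(r$lengths)
          starts <- ends - r$lengths + 1L
          free <- which(!r$values & r$lengths >= u)
          if (!length(free))
            stop(sprintf(
              "repeat_fraction %.2f unattainable: achieved %.3f after %d attempts",
              spec$repeat_fraction, covered / spec$length, attempts))
          nopts <- r$lengths[free] - u + 1L
          pick <- sample.int(sum(nopts), 1L)
          seg <- findInterval(pick - 1L, cumsum(c(0L, nopts)),
                              rightmost.closed = FALSE)
          st <- starts[free[seg]] + (pick - cumsum(c(0L, nopts))[seg] - 1L)
          placed <- TRUE
        }
        div <- stats::runif(1, 0, 0.05)
        copy <- mutate_seq(fams[fam], round(div * u))
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-") copy <- revcomp(copy)
        substr(g, st, st + u - 1L) <- copy
        occ[st:(st + u - 1L)] <- TRUE
        covered <- covered + u
        ann <- rbind(ann, data.frame(start = st - 1L, end = st + u - 1L,
                                     family = paste0("repfam", fam),
                                     strand = strand, stringsAsFactors = FALSE))
      }
      ann <- ann[order(ann$start), , drop = FALSE]
      rownames(ann) <- NULL
    }
    list(genome = seq_records("genome", g), repeats = ann)
  })
}

#' Plan one EVE integration
#'
#' Modes mirror the element structures this kind of screen recovers: `full`
#' (intact element), `five_prime_truncated` (first `truncation_len` bp
#' missing), `fusion` (5' half of `eve_id` joined to the whole
#' `partner_eve_id`, the ALFE4-like structure), and `interrupted` (a host/
#' retroelement-like insert of `insert_len` bp splitting the element in two).
#' Each integration is flanked by 1-kb host-like segments;
#' `flank_copy_number - 1` extra copies of each flank (without the element)
#' are inserted elsewhere in the genome, emulating integration inside
#' multicopy DNA. `sirna` flags the locus's flanks as a source of 21-nt
#' siRNAs for [simulate_small_rna].
#'
#' @param eve_id id of a seed EVE reference.
#' @param mode one of `"full"`, `"five_prime_truncated"`, `"fusion"`,
#'   `"interrupted"`.
#' @param truncation_len bp removed from the 5' end (truncated mode).
#' @param partner_eve_id second element id (fusion mode).
#' @param insert_len bp of interposed sequence (interrupted mode).
#' @param flank_copy_number total genome copies of each flanking segment
#'   (>= 1; 1 means single-copy flanks).
#' @param strand `"+"` or `"-"`: orientation of the element in the genome.
#' @param sirna logical; mark this locus's flanks as siRNA-producing.
#' @return An `integration_plan` list.
#' @export
integration_plan <- function(eve_id, mode = c("full", "five_prime_truncated",
                                              "fusion", "interrupted"),
                             truncation_len = 200L, partner_eve_id = NULL,
                             insert_len = 800L, flank_copy_number = 1L,
                             strand = "+", sirna = FALSE) {
  mode <- match.arg(mode)
  if (mode == "fusion" && is.null(partner_eve_id))
    stop("fusion mode requires partner_eve_id")
  stopifnot(flank_copy_number >= 1, strand %in% c("+", "-"))
  structure(list(eve_id = eve_id, mode = mode,
                 truncation_len = as.integer(truncation_len),
                 partner_eve_id = partner_eve_id,
                 insert_len = as.integer(insert_len),
                 flank_copy_number = as.integer(flank_copy_number),
                 strand = strand, sirna = isTRUE(sirna)),
            class = "integration_plan")
}

# shift 0-based half-open intervals for an insertion of length l before pos;
# stretch = TRUE grows intervals that span the insertion point
.shift_iv <- function(df, pos, l, stretch = FALSE) {
  if (is.null(df) || !nrow(df)) return(df)
  spans <- df$start < pos & df$end > pos
  after <- df$start >= pos
  df$start[after] <- df$start[after] + l
  df$end[after] <- df$end[after] + l
  if (stretch) df$end[spans & !after] <- df$end[spans & !after] + l
  df
}

.insert_at <- function(g, pos, piece) {  # 0-based insertion point
  paste0(substr(g, 1L, pos), piece, substr(g, pos + 1L, nchar(g)))
}

#' Integrate planned EVEs into a genome
#'
#' Each plan inserts `left_flank + element + right_flank` (flanks are 1-kb
#' GC-matched random host-like segments) at a random point inside a
#' repeat-annotated region, then inserts the extra flank copies elsewhere.
#' Insertion points never fall inside previously inserted material, and all
#' recorded coordinates are shifted to stay consistent with the final genome.
#'
#' @param genome the list returned by [make_repeat_rich_genome] (genome +
#'   repeat annotation).
#' @param eve_refs [seq_records] of seed EVE sequences (forward strand =
#'   viral ORF sense).
#' @param plans list of [integration_plan]s.
#' @param seed integer seed.
#' @param flank_len flank length per side (default 1000).
#' @return `list(genome = seq_records, truth = data.frame)`. `truth` has one
#'   row per plan with 0-based half-open `start`/`end` of the inserted
#'   element, `strand`, `mode`, `flank_copy_number`, `sirna`, and list
#'   columns `flank_intervals` (data.frame: start, end, side, copy; copy 0 =
#'   the in-situ flank) and `segments` (element-internal structure:
#'   start, end, label).
#' @export
integrate_eves <- function(genome, eve_refs, plans, seed = 1L,
                           flank_len = 1000L) {
  if (inherits(genome, "seq_records")) genome <- list(genome = genome,
                                                      repeats = NULL)
  stopifnot(is.list(plans))
  if (!length(plans)) {
    truth <- .empty_truth()
    return(list(genome = genome$genome, truth = truth))
  }
  eves <- .seqs(eve_refs)
  for (p in plans) {
    if (!p$eve_id %in% names(eves)) stop("unknown eve_id: ", p$eve_id)
    if (!is.null(p$partner_eve_id) && !p$partner_eve_id %in% names(eves))
      stop("unknown partner_eve_id: ", p$partner_eve_id)
  }
  reps <- genome$repeats
  if (is.null(reps) || !nrow(reps))
    stop("no repeat region large enough: genome has no repeat annotation")
  with_seed(seed, {
    g <- genome$genome$seq[1]
    gc_obs <- .gc_of(g)
    protected <- data.frame(start = integer(), end = integer())
    rows <- list()
    for (pi in seq_along(plans)) {
      p <- plans[[pi]]
      comp <- .compose_element(p, eves, gc_obs)
      eseq <- comp$seq
      segs <- comp$segments
      if (p$strand == "-") {
        eseq <- revcomp(eseq)
        L <- nchar(eseq)
        segs <- data.frame(start = L - segs$end, end = L - segs$start,
                           label = segs$label, stringsAsFactors = FALSE)
        segs <- segs[order(segs$start), , drop = FALSE]
      }
      left <- random_seq(flank_len, gc_obs)
      right <- random_seq(flank_len, gc_obs)
      piece <- paste0(left, eseq, right)
      lp <- nchar(piece)
      pos <- .pick_repeat_pos(reps, protected, nchar(g))
      g <- .insert_at(g, pos, piece)
      reps <- .shift_iv(reps, pos, lp, stretch = TRUE)
      protected <- .shift_iv(protected, pos, lp)
      rows <- lapply(rows, .shift_truth_row, pos = pos, l = lp)
      el_start <- pos + flank_len
      el_end <- el_start + nchar(eseq)
      fl <- data.frame(start = c(pos, el_end),
                       end = c(el_start, pos + lp),
                       side = c("left", "right"), copy = c(0L, 0L),
                       stringsAsFactors = FALSE)
      protected <- rbind(protected,
                         data.frame(start = pos, end = pos + lp))
      segs$start <- segs$start + el_start
      segs$end <- segs$end + el_start
      row <- list(eve_id = p$eve_id, contig = genome$genome$id[1],
                  start = el_start, end = el_end, strand = p$strand,
                  mode = p$mode, flank_copy_number = p$flank_copy_number,
                  sirna = p$sirna, flank_intervals = fl, segments = segs)
      # extra flank copies, inserted anywhere outside protected material
      for (cp in seq_len(p$flank_copy_number - 1L)) {
        for (side in c("left", "right")) {
          fseq <- if (side == "left") left else right
          pos2 <- .pick_free_pos(protected, nchar(g))
          g <- .insert_at(g, pos2, fseq)
          reps <- .shift_iv(reps, pos2, flank_len, stretch = TRUE)
          protected <- .shift_iv(protected, pos2, flank_len)
          rows <- lapply(rows, .shift_truth_row, pos = pos2, l = flank_len)
          row <- .shift_truth_row(row, pos2, flank_len)
          row$flank_intervals <- rbind(
            row$flank_intervals,
            data.frame(start = pos2, end = pos2 + flank_len,
                       side = side, copy = cp, stringsAsFactors = FALSE))
          protected <- rbind(protected,
                             data.frame(start = pos2, end = pos2 + flank_len))
        }
      }
      rows[[pi]] <- row
    }
    truth <- .rows_to_truth(rows)
    list(genome = seq_records(genome$genome$id[1], g), truth = truth)
  })
}

.gc_of <- function(g) {
  n <- nchar(g)
  if (!n) return(0.5)
  (n - nchar(gsub("[GC]", "", g))) / n
}

.compose_element <- function(p, eves, gc) {
  a <- eves[[p$eve_id]]
  seg <- function(s, e, lab) data.frame(start = s, end = e, label = lab,
                                        stringsAsFactors = FALSE)
  switch(p$mode,
    full = list(seq = a, segments = seg(0L, nchar(a), p$eve_id)),
    five_prime_truncated = {
      if (p$truncation_len >= nchar(a))
        stop("truncation_len removes the whole element")
      s <- substr(a, p$truncation_len + 1L, nchar(a))
      list(seq = s, segments = seg(0L, nchar(s), p$eve_id))
    },
    fusion = {
      b <- eves[[p$partner_eve_id]]
      half <- substr(a, 1L, nchar(a) %/% 2L)
      list(seq = paste0(half, b),
           segments = rbind(seg(0L, nchar(half), p$eve_id),
                            seg(nchar(half), nchar(half) + nchar(b),
                                p$partner_eve_id)))
    },
    interrupted = {
      h <- nchar(a) %/% 2L
      ins <- random_seq(p$insert_len, gc)
      list(seq = paste0(substr(a, 1L, h), ins, substr(a, h + 1L, nchar(a))),
           segments = rbind(seg(0L, h, p$eve_id),
                            seg(h, h + p$insert_len, "insert"),
                            seg(h + p$insert_len,
                                h + p$insert_len + (nchar(a) - h), p$eve_id)))
    })
}

.inside_protected <- function(pos, protected) {
  nrow(protected) > 0 && any(pos > protected$start & pos < protected$end)
}

.pick_repeat_pos <- function(reps, protected, glen) {
  for (try in 1:200) {
    r <- reps[sample.int(nrow(reps), 1L), ]
    if (r$end - r$start < 2L) next
    pos <- r$start + sample.int(r$end - r$start - 1L, 1L)
    if (!.inside_protected(pos, protected)) return(pos)
  }
  stop("no repeat region large enough for integration")
}

.pick_free_pos <- function(protected, glen) {
  for (try in 1:200) {
    pos <- sample.int(glen + 1L, 1L) - 1L
    if (!.inside_protected(pos, protected)) return(pos)
  }
  stop("could not place flank copy outside existing insertions")
}

.shift_truth_row <- function(row, pos, l) {
  sh <- function(x) ifelse(x >= pos, x + l, x)
  row$start <- sh(row$start); row$end <- sh(row$end)
  row$flank_intervals <- .shift_iv(row$flank_intervals, pos, l)
  row$segments <- .shift_iv(row$segments, pos, l)
  row
}

.empty_truth <- function() {
  t <- data.frame(eve_id = character(), contig = character(),
                  start = integer(), end = integer(), strand = character(),
                  mode = character(), flank_copy_number = integer(),
                  sirna = logical(), stringsAsFactors = FALSE)
  t$flank_intervals <- list(); t$segments <- list()
  class(t) <- c("integration_truth", "data.frame")
  t
}

.rows_to_truth <- function(rows) {
  t <- data.frame(eve_id = vapply(rows, `[[`, "", "eve_id"),
                  contig = vapply(rows, `[[`, "", "contig"),
                  start = vapply(rows, `[[`, 0L, "start"),
                  end = vapply(rows, `[[`, 0L, "end"),
                  strand = vapply(rows, `[[`, "", "strand"),
                  mode = vapply(rows, `[[`, "", "mode"),
                  flank_copy_number = vapply(rows, `[[`, 0L,
                                             "flank_copy_number"),
                  sirna = vapply(rows, `[[`, FALSE, "sirna"),
                  stringsAsFactors = FALSE)
  t$flank_intervals <- lapply(rows, `[[`, "flank_intervals")
  t$segments <- lapply(rows, `[[`, "segments")
  class(t) <- c("integration_truth", "data.frame")
  t
}

#' Paired-end DNA read model
#'
#' Defaults mirror a standard short-insert shotgun library: 200-bp fragments
#' sequenced as 2 x 151 paired ends.
#'
#' @param fragment_len_mean,fragment_len_sd fragment length distribution (bp).
#' @param read_len read length (must be <= mean + 4*sd).
#' @param n_pairs number of read pairs.
#' @param error_rate per-base substitution probability, in [0, 0.1].
#' @param seed integer seed.
#' @return A `dna_read_model` list.
#' @export
dna_read_model <- function(fragment_len_mean = 200L, fragment_len_sd = 20L,
                           read_len = 151L, n_pairs = 1000L,
                           error_rate = 0.005, seed = 1L) {
  stopifnot(error_rate >= 0, error_rate <= 0.1,
            read_len <= fragment_len_mean + 4 * fragment_len_sd,
            read_len >= 1, n_pairs >= 0)
  structure(list(fragment_len_mean = fragment_len_mean,
                 fragment_len_sd = fragment_len_sd,
                 read_len = as.integer(read_len),
                 n_pairs = as.integer(n_pairs),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "dna_read_model")
}

# substitute bases at given per-read error rate; vectorized over reads
.add_errors <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  nerr <- stats::rbinom(length(seqs), nchar(seqs), rate)
  idx <- which(nerr > 0)
  for (i in idx) seqs[i] <- mutate_seq(seqs[i], nerr[i])
  seqs
}

#' Simulate paired-end DNA reads
#'
#' Fragments have normal lengths (truncated at `read_len`), uniform start
#' positions, and uniform strand; `r1` is the fragment 5' end, `r2` the
#' reverse complement of the fragment 3' end. Substitution errors at
#' `error_rate`; constant quality 37.
#'
#' @param genome a [seq_records] genome (or the list from
#'   [make_repeat_rich_genome] / [integrate_eves]).
#' @param model a [dna_read_model].
#' @return `list(r1, r2, truth)`: two [seq_records] tables and a truth
#'   data.frame (`pair_id`, 0-based `start`, `frag_len`, `strand`).
#' @export
simulate_dna_reads <- function(genome, model) {
  stopifnot(inherits(model, "dna_read_model"))
  g <- .genome_seq(genome)
  L <- nchar(g)
  stopifnot(L > model$fragment_len_mean)
  with_seed(model$seed, {
    n <- model$n_pairs
    if (n == 0L) {
      e <- seq_records(character(), character(),
                       qual = list())
      return(list(r1 = e, r2 = e,
                  truth = data.frame(pair_id = character(), start = integer(),
                                     frag_len = integer(), strand = character(),
                                     stringsAsFactors = FALSE)))
    }
    fl <- pmax(model$read_len,
               pmin(L, round(stats::rnorm(n, model$fragment_len_mean,
                                          model$fragment_len_sd))))
    st <- floor(stats::runif(n) * (L - fl + 1))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    frag <- substring(g, st + 1, st + fl)
    frag[strand == "-"] <- revcomp(frag[strand == "-"])
    r1 <- substring(frag, 1L, model$read_len)
    r2 <- substring(revcomp(frag), 1L, model$read_len)
    r1 <- .add_errors(r1, model$error_rate)
    r2 <- .add_errors(r2, model$error_rate)
    pid <- sprintf("frag%06d", seq_len(n))
    list(r1 = seq_records(paste0(pid, "/1"), r1, qual = 37L),
         r2 = seq_records(paste0(pid, "/2"), r2, qual = 37L),
         truth = data.frame(pair_id = pid, start = st, frag_len = fl,
                            strand = strand, stringsAsFactors = FALSE))
  })
}

.genome_seq <- function(genome) {
  if (is.list(genome) && !is.null(genome$genome) &&
      inherits(genome$genome, "seq_records"))
    return(genome$genome$seq[1])
  if (inherits(genome, "seq_records")) return(genome$seq[1])
  if (is.character(genome)) return(genome[1])
  stop("expected a genome seq_records or generator result")
}

#' Small-RNA library model
#'
#' Emulates the small-RNA signature over an EVE locus: a dominant class of
#' piRNA-like reads (lengths from a discretized normal, default mean 28 sd 1
#' truncated to 25--31 nt) oriented antisense to the element's viral-ORF
#' sense with probability `antisense_fraction`, whose 5' base is overwritten
#' to T with probability `u1_prob` and to a random non-T base otherwise, so
#' the realized first-position T frequency equals `u1_prob` (the
#' primary-piRNA 1U bias); an optional
#' 21-nt siRNA class restricted to the flanks of loci flagged `sirna` in the
#' integration truth; and uniform background reads.
#'
#' @param pirna_len_mean,pirna_len_sd,pirna_len_range piRNA length model
#'   (range inclusive, within [18, 35]).
#' @param antisense_fraction probability a piRNA read is antisense.
#' @param u1_prob realized first-position T frequency of piRNA reads.
#' @param sirna_len siRNA length (nt).
#' @param sirna_strand_balance probability an siRNA read is sense-oriented.
#' @param sirna_fraction fraction of non-background reads drawn from the
#'   siRNA class when at least one locus is flagged (else 0).
#' @param background_rate fraction of reads drawn uniformly from the genome
#'   (default 0: the default library is the pure locus signature).
#' @param n_reads total reads.
#' @param seed integer seed.
#' @return A `small_rna_model` list.
#' @export
small_rna_model <- function(pirna_len_mean = 28, pirna_len_sd = 1.0,
                            pirna_len_range = c(25L, 31L),
                            antisense_fraction = 1.0, u1_prob = 0.7,
                            sirna_len = 21L, sirna_strand_balance = 0.5,
                            sirna_fraction = 0.2, background_rate = 0,
                            n_reads = 10000L, seed = 1L) {
  stopifnot(antisense_fraction >= 0, antisense_fraction <= 1,
            u1_prob >= 0, u1_prob <= 1,
            sirna_strand_balance >= 0, sirna_strand_balance <= 1,
            sirna_fraction >= 0, sirna_fraction <= 1,
            background_rate >= 0, background_rate <= 1,
            pirna_len_range[1] >= 18, pirna_len_range[2] <= 35,
            pirna_len_range[1] <= pirna_len_range[2], n_reads >= 0)
  structure(list(pirna_len_mean = pirna_len_mean, pirna_len_sd = pirna_len_sd,
                 pirna_len_range = as.integer(pirna_len_range),
                 antisense_fraction = antisense_fraction, u1_prob = u1_prob,
                 sirna_len = as.integer(sirna_len),
                 sirna_strand_balance = sirna_strand_balance,
                 sirna_fraction = sirna_fraction,
                 background_rate = background_rate,
                 n_reads = as.integer(n_reads), seed = as.integer(seed)),
            class = "small_rna_model")
}

#' Discretized truncated-normal piRNA length probabilities
#'
#' @param model a [small_rna_model].
#' @return Named numeric vector of probabilities over the length range.
#' @export
pirna_length_probs <- function(model) {
  lens <- model$pirna_len_range[1]:model$pirna_len_range[2]
  p <- stats::pnorm(lens + 0.5, model$pirna_len_mean, model$pirna_len_sd) -
    stats::pnorm(lens - 0.5, model$pirna_len_mean, model$pirna_len_sd)
  stats::setNames(p / sum(p), lens)
}

#' Simulate a small-RNA library
#'
#' Class counts are fixed fractions of `n_reads` (background first, then the
#' siRNA share of the remainder when any locus is flagged); all draws are
#' deterministic given `model$seed`. Reads are emitted in the DNA alphabet,
#' as sequenced. The returned records carry a `truth` attribute
#' (read class, genomic interval, genomic strand, source locus).
#'
#' @param genome2 integrated genome ([integrate_eves] result or
#'   [seq_records]).
#' @param truth the `integration_truth` table.
#' @param model a [small_rna_model].
#' @return A [seq_records] table with constant quality 37 and attribute
#'   `truth`.
#' @export
simulate_small_rna <- function(genome2, truth, model) {
  stopifnot(inherits(model, "small_rna_model"))
  g <- .genome_seq(genome2)
  L <- nchar(g)
  if (!nrow(truth) && model$background_rate < 1)
    stop("truth is empty: only background reads (background_rate = 1) can be simulated")
  with_seed(model$seed, {
    n <- model$n_reads
    if (n == 0L)
      return(structure(seq_records(character(), character(), list()),
                       truth = NULL))
    n_bg <- round(model$background_rate * n)
    flagged <- nrow(truth) > 0 && any(truth$sirna)
    n_si <- if (flagged) round(model$sirna_fraction * (n - n_bg)) else 0L
    n_pi <- n - n_bg - n_si

    mk <- function(start, len, genomic_strand, class, locus) {
      s <- substring(g, start + 1, start + len)
      s[genomic_strand == "-"] <- revcomp(s[genomic_strand == "-"])
      list(seq = s,
           truth = data.frame(class = class, start = start, len = len,
                              genomic_strand = genomic_strand, locus = locus,
                              stringsAsFactors = FALSE))
    }

    parts <- list()
    if (n_pi > 0) {
      li <- sample.int(nrow(truth), n_pi, replace = TRUE)
      span <- t(vapply(seq_len(nrow(truth)), function(i) {
        fl <- truth$flank_intervals[[i]]
        adj <- fl[fl$copy == 0L, ]
        c(min(adj$start), max(adj$end))
      }, numeric(2)))
      probs <- pirna_length_probs(model)
      len <- as.integer(sample(names(probs), n_pi, replace = TRUE,
                               prob = probs))
      lo <- span[li, 1]; hi <- span[li, 2]
      start <- lo + floor(stats::runif(n_pi) * pmax(1, hi - lo - len + 1))
      anti <- stats::runif(n_pi) < model$antisense_fraction
      elem_strand <- truth$strand[li]
      # antisense read = revcomp of the locus sense strand at that window
      genomic_strand <- ifelse(xor(elem_strand == "-", anti), "-", "+")
      p <- mk(start, len, genomic_strand, "piRNA", truth$eve_id[li])
      u1 <- stats::runif(n_pi) < model$u1_prob
      substr(p$seq[u1], 1L, 1L) <- "T"
      notT <- sample(c("A", "C", "G"), n_pi, replace = TRUE)
      for (i in which(!u1)) substr(p$seq[i], 1L, 1L) <- notT[i]
      parts$pi <- p
    }
    if (n_si > 0) {
      fls <- do.call(rbind, lapply(which(truth$sirna), function(i) {
        fl <- truth$flank_intervals[[i]]
        fl <- fl[fl$copy == 0L, ]
        fl$locus <- truth$eve_id[i]; fl$elem_strand <- truth$strand[i]
        fl
      }))
      fi <- sample.int(nrow(fls), n_si, replace = TRUE)
      len <- rep.int(model$sirna_len, n_si)
      start <- fls$start[fi] +
        floor(stats::runif(n_si) * pmax(1, fls$end[fi] - fls$start[fi] - len + 1))
      sense <- stats::runif(n_si) < model$sirna_strand_balance
      genomic_strand <- ifelse(xor(fls$elem_strand[fi] == "-", !sense),
                               "-", "+")
      parts$si <- mk(start, len, genomic_strand, "siRNA", fls$locus[fi])
    }
    if (n_bg > 0) {
      len <- sample(18:35, n_bg, replace = TRUE)
      start <- floor(stats::runif(n_bg) * (L - len + 1))
      genomic_strand <- sample(c("+", "-"), n_bg, replace = TRUE)
      parts$bg <- mk(start, len, genomic_strand, "background",
                     NA_character_)
    }
    seqs <- unlist(lapply(parts, `[[`, "seq"), use.names = FALSE)
    tr <- do.call(rbind, lapply(parts, `[[`, "truth"))
    ord <- sample.int(length(seqs))
    seqs <- seqs[ord]; tr <- tr[ord, , drop = FALSE]
    tr$id <- sprintf("sr%06d", seq_along(seqs))
    rownames(tr) <- NULL
    out <- seq_records(tr$id, seqs, qual = 37L)
    attr(out, "truth") <- tr
    out
  })
}
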