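#' Configuration of the iterative discovery screen
#'
#' Bundles every threshold of the recruit -> assemble -> length-filter ->
#' re-seed loop: the E-value cutoff for read recruitment (1e-20), the contig
#' length filter (strictly greater than 400 bases), the iteration cap (5 —
#' matches explode in repetitive flanking DNA, so the loop is bounded), the
#' duplicate-contig criterion, and the annotation/presence thresholds.
#'
#' @param e_max recruitment E-value threshold.
#' @param min_contig_len contig length filter (strict).
#' @param max_iterations iteration cap.
#' @param dedupe_identity,dedupe_coverage duplicate criterion: a contig is a
#'   duplicate when word-match chains to a longer retained contig cover at
#'   least `dedupe_coverage` of its length at `dedupe_identity` identity.
#' @param recruit_cap maximum recruited reads per iteration; excess is cut
#'   to the highest-scoring reads (logged).
#' @param k,min_kmer_count assembler sub-configuration.
#' @param scoring a [scoring_params] for recruitment and annotation.
#' @param annotate_min_identity minimum identity for an EVE-labeled segment.
#' @param min_segment minimum annotated segment length (nt).
#' @param map_min_identity,min_aligned DNA-mapping thresholds for presence
#'   calls.
#' @param presence_cov covered fraction at or above which (absent
#'   disqualifying gaps) an element is called present.
#' @param presence_gap maximum internal zero-depth gap (nt) for a present
#'   call.
#' @param partial_cov covered fraction at or above which a non-present
#'   element is called partial.
#' @param mate_rescue recruit both mates when either matches.
#' @param seed tie-breaking seed for mapping.
#' @return A `screen_config` list.
#' @export
screen_config <- function(e_max = 1e-20, min_contig_len = 400L,
                          max_iterations = 5L, dedupe_identity = 0.95,
                          dedupe_coverage = 0.90, recruit_cap = 200000L,
                          k = 31L, min_kmer_count = 3L,
                          scoring = scoring_params(),
                          annotate_min_identity = 0.8, min_segment = 30L,
                          map_min_identity = 0.9, min_aligned = 100L,
                          presence_cov = 0.95, presence_gap = 50L,
                          partial_cov = 0.3, mate_rescue = TRUE,
                          seed = 1L) {
  stopifnot(e_max > 0, max_iterations >= 1, dedupe_identity > 0,
            dedupe_identity <= 1, dedupe_coverage > 0, dedupe_coverage <= 1,
            min_contig_len >= 1)
  structure(list(e_max = e_max, min_contig_len = as.integer(min_contig_len),
                 max_iterations = as.integer(max_iterations),
                 dedupe_identity = dedupe_identity,
                 dedupe_coverage = dedupe_coverage,
                 recruit_cap = as.integer(recruit_cap),
                 k = as.integer(k), min_kmer_count = as.integer(min_kmer_count),
                 scoring = scoring,
                 annotate_min_identity = annotate_min_identity,
                 min_segment = as.integer(min_segment),
                 map_min_identity = map_min_identity,
                 min_aligned = as.integer(min_aligned),
                 presence_cov = presence_cov,
                 presence_gap = as.integer(presence_gap),
                 partial_cov = partial_cov, mate_rescue = mate_rescue,
                 seed = as.integer(seed)),
            class = "screen_config")
}

#' One iteration of the discovery loop
#'
#' recruit -> extract -> assemble -> length-filter. When more than
#' `cfg$recruit_cap` reads are recruited, only the highest-scoring
#' `recruit_cap` (rescued mates inherit their mate's score) are kept and the
#' cap event is logged.
#'
#' @param queries [seq_records] of query sequences (non-empty).
#' @param reads [seq_records] or paired list with `r1`/`r2`.
#' @param cfg a [screen_config].
#' @return Contig data.frame (see [assemble_reads]) with attribute `log`:
#'   `n_queries`, `n_reads`, `n_recruited`, `capped`, `n_hits`,
#'   `n_contigs`.
#' @export
run_iteration <- function(queries, reads, cfg = screen_config()) {
  recs <- .flatten_reads(reads)
  rec <- recruit_reads(queries, recs, cfg$scoring, cfg$e_max,
                       cfg$mate_rescue)
  ids <- rec$recruited
  capped <- FALSE
  if (length(ids) > cfg$recruit_cap) {
    capped <- TRUE
    keep <- names(sort(rec$best_score, decreasing = TRUE))[
      seq_len(cfg$recruit_cap)]
    ids <- ids[ids %in% keep]
  }
  sub <- recs[recs$id %in% ids, , drop = FALSE]
  contigs <- filter_contigs(assemble_reads(sub, cfg$k, cfg$min_kmer_count),
                            cfg$min_contig_len)
  attr(contigs, "log") <- list(
    n_queries = length(.seqs(queries)), n_reads = nrow(recs),
    n_recruited = length(ids), capped = capped,
    n_hits = if (is.null(rec$hits)) 0L else nrow(rec$hits),
    max_evalue_recruited = if (!is.null(rec$hits) && nrow(rec$hits))
      max(rec$hits$evalue) else NA_real_,
    n_contigs = nrow(contigs))
  contigs
}

# union length of 0-based half-open intervals
.iv_union_len <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  tot <- 0L; cs <- start[1]; ce <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] > ce) { tot <- tot + (ce - cs); cs <- start[i]; ce <- end[i] }
    else ce <- max(ce, end[i])
  }
  tot + (ce - cs)
}

#' Remove duplicate contigs
#'
#' Contigs are processed longest-first (ties lexicographic); a contig is a
#' duplicate when, against some retained (longer or equal) contig, its
#' ungapped word-match chain at identity >= `identity` covers at least
#' `coverage` of its length on either strand.
#'
#' @param contigs contig data.frame (needs `seq`; other columns carried
#'   through).
#' @param identity per-chain identity threshold.
#' @param coverage covered-fraction threshold.
#' @param scoring a [scoring_params].
#' @return The retained contigs, longest-first, with ids reassigned
#'   `contig_1..n`.
#' @export
dedupe_contigs <- function(contigs, identity = 0.95, coverage = 0.90,
                           scoring = scoring_params()) {
  stopifnot(identity > 0, identity <= 1, coverage > 0, coverage <= 1)
  if (!nrow(contigs)) return(contigs)
  ord <- order(-nchar(contigs$seq), contigs$seq)
  contigs <- contigs[ord, , drop = FALSE]
  retained <- integer(0)
  for (i in seq_len(nrow(contigs))) {
    dup <- FALSE
    if (length(retained)) {
      h <- cpp_seed_extend(contigs$seq[i], contigs$seq[retained],
                           scoring$word_size, scoring$match,
                           scoring$mismatch, scoring$xdrop)
      if (nrow(h)) {
        len <- h$q_end - h$q_start
        h <- h[len > 0 & h$matches / len >= identity, , drop = FALSE]
        if (nrow(h)) {
          for (q in unique(h$query)) {
            hq <- h[h$query == q, , drop = FALSE]
            cov <- .iv_union_len(hq$s_start, hq$s_end) /
              nchar(contigs$seq[i])
            agg <- sum(hq$matches) / sum(hq$q_end - hq$q_start)
            if (cov >= coverage && agg >= identity) { dup <- TRUE; break }
          }
        }
      }
    }
    if (!dup) retained <- c(retained, i)
  }
  out <- contigs[retained, , drop = FALSE]
  out$id <- paste0("contig_", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

# subtract covered intervals from [a, b); returns remaining pieces
.iv_subtract <- function(a, b, covered) {
  if (is.null(covered) || !nrow(covered)) {
    return(data.frame(start = a, end = b))
  }
  covered <- covered[order(covered$start), , drop = FALSE]
  pieces <- data.frame(start = integer(), end = integer())
  cur <- a
  for (i in seq_len(nrow(covered))) {
    cs <- max(covered$start[i], a); ce <- min(covered$end[i], b)
    if (ce <= cs) next
    if (cs > cur) pieces <- rbind(pieces, data.frame(start = cur, end = cs))
    cur <- max(cur, ce)
  }
  if (cur < b) pieces <- rbind(pieces, data.frame(start = cur, end = b))
  pieces
}

#' Segment a contig into EVE-derived and flanking intervals
#'
#' Aligns every EVE reference to the contig on both strands; maximal
#' non-overlapping hit intervals at identity >= `min_identity` become
#' EVE-labeled segments (overlaps resolved by score, ties by lower start;
#' lower-scoring hits are trimmed to their non-overlapping remainder), and
#' residual intervals are labeled `non-EVE`. Segments tile the contig;
#' adjacent segments with identical label and strand are merged.
#'
#' @param contig one contig: a one-row contig data.frame, a single-record
#'   [seq_records], or a named sequence.
#' @param eve_refs [seq_records] of EVE references (non-empty).
#' @param min_identity minimum segment identity (default 0.8).
#' @param min_segment minimum EVE segment length (default 30 nt).
#' @param scoring a [scoring_params].
#' @return An `annotated_contig` list: `id`, `seq`, `segments` (0-based
#'   half-open `start`, `end`, `label`, `strand`, `identity`),
#'   `iteration_found` (NA until set by [iterative_screen]).
#' @export
annotate_contig <- function(contig, eve_refs, min_identity = 0.8,
                            min_segment = 30L,
                            scoring = scoring_params()) {
  cs <- .seqs(contig)
  stopifnot(length(cs) == 1L)
  eves <- .seqs(eve_refs)
  if (!length(eves)) stop("eve_refs is empty")
  L <- nchar(cs)
  h <- cpp_seed_extend(unname(cs), unname(eves), scoring$word_size,
                       scoring$match, scoring$mismatch, scoring$xdrop)
  segs <- data.frame(start = integer(), end = integer(), label = character(),
                     strand = character(), identity = numeric(),
                     stringsAsFactors = FALSE)
  if (nrow(h)) {
    len <- h$q_end - h$q_start
    h$identity <- ifelse(len > 0, h$matches / len, 0)
    h <- h[h$identity >= min_identity & len >= min_segment, , drop = FALSE]
    h <- h[order(-h$score, h$s_start), , drop = FALSE]
    accepted <- data.frame(start = integer(), end = integer())
    for (i in seq_len(nrow(h))) {
      pieces <- .iv_subtract(h$s_start[i], h$s_end[i], accepted)
      pieces <- pieces[pieces$end - pieces$start >= min_segment, ,
                       drop = FALSE]
      if (!nrow(pieces)) next
      segs <- rbind(segs, data.frame(
        start = pieces$start, end = pieces$end,
        label = names(eves)[h$query[i]], strand = h$strand[i],
        identity = h$identity[i], stringsAsFactors = FALSE))
      accepted <- rbind(accepted, pieces[, c("start", "end")])
    }
  }
  segs <- segs[order(segs$start), , drop = FALSE]
  # fill residual intervals with non-EVE, then merge equal neighbors
  tiles <- data.frame(start = integer(), end = integer(), label = character(),
                      strand = character(), identity = numeric(),
                      stringsAsFactors = FALSE)
  cur <- 0L
  for (i in seq_len(nrow(segs))) {
    if (segs$start[i] > cur)
      tiles <- rbind(tiles, data.frame(start = cur, end = segs$start[i],
                                       label = "non-EVE", strand = "+",
                                       identity = NA_real_))
    tiles <- rbind(tiles, segs[i, ])
    cur <- segs$end[i]
  }
  if (cur < L)
    tiles <- rbind(tiles, data.frame(start = cur, end = L, label = "non-EVE",
                                     strand = "+", identity = NA_real_))
  if (nrow(tiles) > 1L) {
    keep <- rep(TRUE, nrow(tiles))
    for (i in 2:nrow(tiles)) {
      j <- max(which(keep[1:(i - 1)]))
      if (tiles$label[i] == tiles$label[j] &&
          tiles$strand[i] == tiles$strand[j]) {
        tiles$end[j] <- tiles$end[i]
        keep[i] <- FALSE
      }
    }
    tiles <- tiles[keep, , drop = FALSE]
  }
  rownames(tiles) <- NULL
  structure(list(id = names(cs), seq = unname(cs), segments = tiles,
                 iteration_found = NA_integer_),
            class = "annotated_contig")
}

#' The iterative discovery screen
#'
#' Runs [run_iteration] up to `cfg$max_iterations` times: the first
#' iteration uses the seed EVEs as queries; each later iteration uses the
#' deduplicated union of all contigs found so far, so that contigs walk
#' outward from the seed elements into their flanking sequence. The loop
#' stops early when an iteration contributes no new (non-duplicate) contig.
#' Every final contig is annotated against the seed EVEs and tagged with the
#' iteration at which it first appeared.
#'
#' @param seed_eves [seq_records] of seed EVE sequences (non-empty).
#' @param reads [seq_records] or paired list with `r1`/`r2`.
#' @param cfg a [screen_config].
#' @return An `eve_screen` list: `contigs` (data.frame with
#'   `iteration_found`), `annotations` (named list of segment data.frames),
#'   `log` (one entry per executed iteration).
#' @export
iterative_screen <- function(seed_eves, reads, cfg = screen_config()) {
  if (!length(.seqs(seed_eves))) stop("seed_eves is empty")
  reads <- .flatten_reads(reads)
  all <- cbind(.empty_contigs(), iteration_found = integer())
  queries <- seed_eves
  logs <- list()
  for (it in seq_len(cfg$max_iterations)) {
    contigs <- run_iteration(queries, reads, cfg)
    logs[[it]] <- c(list(iteration = it), attr(contigs, "log"))
    if (!nrow(contigs)) break
    contigs$iteration_found <- it
    combined <- rbind(all, contigs[, names(all)])
    ded <- dedupe_contigs(combined, cfg$dedupe_identity,
                          cfg$dedupe_coverage, cfg$scoring)
    new_seqs <- setdiff(ded$seq, all$seq)
    logs[[it]]$n_new_contigs <- length(new_seqs)
    if (!length(new_seqs)) break
    all <- ded
    queries <- seq_records(all$id, all$seq)
  }
  ann <- lapply(seq_len(nrow(all)), function(i) {
    a <- annotate_contig(stats::setNames(all$seq[i], all$id[i]), seed_eves,
                         cfg$annotate_min_identity, cfg$min_segment,
                         cfg$scoring)
    a$iteration_found <- all$iteration_found[i]
    a
  })
  names(ann) <- all$id
  structure(list(contigs = all, annotations = ann, log = logs),
            class = "eve_screen")
}

#' @export
print.eve_screen <- function(x, ...) {
  cat(sprintf("<eve_screen> %d contig(s) after %d iteration(s)\n",
              nrow(x$contigs), length(x$log)))
  invisible(x)
}

#' Presence calls from depth and continuity of coverage
#'
#' Maps the DNA reads to each element reference independently and calls
#' `present` when the covered fraction reaches `cfg$presence_cov` with no
#' internal zero-depth gap longer than `cfg$presence_gap`, `partial` when
#' the covered fraction reaches `cfg$partial_cov`, else `absent`.
#'
#' @param element_refs [seq_records] of element references.
#' @param reads [seq_records] or paired list with `r1`/`r2`.
#' @param cfg a [screen_config].
#' @param sample_id label recorded on every call.
#' @return data.frame: `sample_id`, `element_id`, `call`,
#'   `covered_fraction`, `max_internal_gap`, `mean_depth`.
#' @export
call_presence <- function(element_refs, reads, cfg = screen_config(),
                          sample_id = "sample1") {
  refs <- .seqs(element_refs)
  reads <- .flatten_reads(reads)
  rows <- lapply(names(refs), function(rid) {
    ref1 <- refs[rid]
    pl <- map_dna_reads(reads, ref1, cfg$scoring, cfg$map_min_identity,
                        cfg$min_aligned, cfg$seed)
    prof <- depth_profile(pl, ref1)
    tot <- prof$depth_fwd + prof$depth_rev
    covered <- mean(tot > 0)
    g <- prof$gaps
    internal <- g[g$start > 0 & g$end < prof$length, , drop = FALSE]
    maxgap <- if (nrow(internal)) max(internal$end - internal$start) else 0L
    call <- if (covered >= cfg$presence_cov && maxgap <= cfg$presence_gap)
      "present" else if (covered >= cfg$partial_cov) "partial" else "absent"
    data.frame(sample_id = sample_id, element_id = rid, call = call,
               covered_fraction = covered, max_internal_gap = maxgap,
               mean_depth = mean(tot), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
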