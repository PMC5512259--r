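#' Place DNA reads on references by best ungapped local alignment
#'
#' Each read (mates placed independently) is aligned to every reference on
#' both strands by seed-and-extend; its best-scoring hit is kept if the
#' aligned identity reaches `min_identity` over at least
#' `min(min_aligned, ceil(2/3 read length))` bases. Score ties are broken
#' uniformly at random under `seed`. The placement interval is the aligned
#' subinterval of the reference.
#'
#' @param reads [seq_records] or a paired list with `r1`/`r2`.
#' @param refs [seq_records] of references (non-empty).
#' @param params a [scoring_params].
#' @param min_identity minimum aligned identity (default 0.9).
#' @param min_aligned minimum aligned length (default 100).
#' @param seed tie-breaking seed.
#' @return data.frame of placements: `read_id`, `ref_id`, `pos` (0-based
#'   start of the aligned interval on the reference), `strand`, `length`
#'   (aligned length), `identity`, `score`, `read_start`/`read_end`
#'   (0-based half-open aligned interval on the read, forward read
#'   coordinates), `seq` (aligned read subsequence, as sequenced).
#'   Unmapped reads are omitted.
#' @export
map_dna_reads <- function(reads, refs, params = scoring_params(),
                          min_identity = 0.9, min_aligned = 100L,
                          seed = 1L) {
  rf <- .seqs(refs)
  if (!length(rf)) stop("empty reference set")
  recs <- .flatten_reads(reads)
  if (!nrow(recs)) return(.empty_dna_placements())
  h <- cpp_seed_extend(recs$seq, unname(rf), params$word_size, params$match,
                       params$mismatch, params$xdrop)
  if (!nrow(h)) return(.empty_dna_placements())
  len <- h$q_end - h$q_start
  h$alen <- len
  h$identity <- ifelse(len > 0, h$matches / len, 0)
  need <- pmin(as.integer(min_aligned),
               as.integer(ceiling(2 / 3 * nchar(recs$seq[h$subject]))))
  keep_rows <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(h)), h$subject), function(ix) {
      sc <- h$score[ix]
      best <- ix[sc == max(sc)]
      ok <- best[h$identity[best] >= min_identity &
                 h$alen[best] >= need[best]]
      if (!length(ok)) return(integer(0))
      if (length(ok) == 1L) ok else ok[sample.int(length(ok), 1L)]
    }), use.names = FALSE)
  })
  if (!length(keep_rows)) return(.empty_dna_placements())
  h <- h[sort(keep_rows), , drop = FALSE]
  data.frame(read_id = recs$id[h$subject], ref_id = names(rf)[h$query],
             pos = h$q_start, strand = h$strand, length = h$alen,
             identity = h$identity, score = h$score,
             read_start = h$s_start, read_end = h$s_end,
             seq = substring(recs$seq[h$subject], h$s_start + 1L, h$s_end),
             stringsAsFactors = FALSE)
}

.empty_dna_placements <- function() {
  data.frame(read_id = character(), ref_id = character(), pos = integer(),
             strand = character(), length = integer(), identity = numeric(),
             score = integer(), seq = character(), stringsAsFactors = FALSE)
}

#' Strand-resolved depth profile and zero-coverage gaps
#'
#' Per-position counts of covering placements by strand, plus the maximal
#' intervals of zero total depth (the uncovered regions a coverage plot
#' renders as gaps).
#'
#' @param placements data.frame of placements on `ref` (from
#'   [map_dna_reads] or [map_small_rna]).
#' @param ref a single-record [seq_records] (or named sequence).
#' @return A `coverage_profile` list: `ref_id`, `length`, `depth_fwd`,
#'   `depth_rev`, `gaps` (0-based half-open data.frame, disjoint, maximal,
#'   sorted).
#' @export
depth_profile <- function(placements, ref) {
  rf <- .seqs(ref)
  stopifnot(length(rf) == 1L)
  L <- nchar(rf)
  if (nrow(placements) && !all(placements$ref_id == names(rf)))
    stop("placements reference a different sequence than ", names(rf))
  depth_of <- function(q) {
    if (!nrow(q)) return(numeric(L))
    add <- tabulate(q$pos + 1L, nbins = L + 1L)
    sub <- tabulate(pmin(q$pos + q$length, L) + 1L, nbins = L + 1L)
    cumsum(add - sub)[seq_len(L)]
  }
  df <- depth_of(placements[placements$strand == "+", , drop = FALSE])
  dr <- depth_of(placements[placements$strand == "-", , drop = FALSE])
  z <- rle((df + dr) == 0)
  ends <- cumsum(z$lengths)
  starts <- ends - z$lengths
  gaps <- data.frame(start = starts[z$values], end = ends[z$values])
  structure(list(ref_id = names(rf), length = L, depth_fwd = df,
                 depth_rev = dr, gaps = gaps),
            class = "coverage_profile")
}

#' Mean total depth over intervals
#'
#' @param profile a [depth_profile] result.
#' @param intervals data.frame/matrix with 0-based half-open `start`, `end`.
#' @return Mean of `depth_fwd + depth_rev` over all interval positions.
#' @export
mean_depth_over <- function(profile, intervals) {
  intervals <- as.data.frame(intervals)
  if (!nrow(intervals)) stop("empty interval set")
  if (any(intervals$start < 0 | intervals$end > profile$length |
          intervals$end <= intervals$start))
    stop("interval outside reference bounds")
  tot <- profile$depth_fwd + profile$depth_rev
  pos <- unlist(Map(function(s, e) (s + 1L):e, intervals$start,
                    intervals$end), use.names = FALSE)
  mean(tot[pos])
}

#' Multicopy-flank inference from relative depth
#'
#' Elements integrated in multicopy regions show flank coverage well above
#' element coverage; the call is `ratio = mean flank depth / mean element
#' depth >= ratio_threshold`. The threshold operationalizes "substantially
#' higher" and is always reported with the raw ratio.
#'
#' @param profile a [depth_profile] result.
#' @param element_interval data.frame/matrix with one 0-based half-open row.
#' @param flank_intervals data.frame/matrix of flank intervals.
#' @param ratio_threshold ratio at or above which the flank is called
#'   multicopy (default 3).
#' @return A `multicopy_call` list: depths, `ratio` (NA when element depth
#'   is zero), `multicopy`, `ratio_defined`, `threshold`.
#' @export
multicopy_call <- function(profile, element_interval, flank_intervals,
                           ratio_threshold = 3.0) {
  ed <- mean_depth_over(profile, element_interval)
  fd <- mean_depth_over(profile, flank_intervals)
  if (ed == 0) {
    return(structure(list(ref_id = profile$ref_id, element_depth = 0,
                          flank_depth = fd, ratio = NA_real_,
                          multicopy = FALSE, ratio_defined = FALSE,
                          threshold = ratio_threshold),
                     class = "multicopy_call"))
  }
  ratio <- fd / ed
  structure(list(ref_id = profile$ref_id, element_depth = ed,
                 flank_depth = fd, ratio = ratio,
                 multicopy = ratio >= ratio_threshold, ratio_defined = TRUE,
                 threshold = ratio_threshold), class = "multicopy_call")
}

#' Write a depth profile as TSV / bedGraph / gaps BED
#'
#' @param profile a [depth_profile] result.
#' @param tsv,bedgraph,gaps_bed output paths (`NULL` skips).
#' @export
write_depth_tracks <- function(profile, tsv = NULL, bedgraph = NULL,
                               gaps_bed = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(
      data.frame(ref = profile$ref_id, position = seq_len(profile$length) - 1L,
                 depth_fwd = profile$depth_fwd, depth_rev = profile$depth_rev),
      tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bedgraph)) {
    tot <- profile$depth_fwd + profile$depth_rev
    r <- rle(tot)
    ends <- cumsum(r$lengths)
    writeLines(sprintf("%s\t%d\t%d\t%g", profile$ref_id,
                       ends - r$lengths, ends, r$values), bedgraph)
  }
  if (!is.null(gaps_bed)) {
    writeLines(if (nrow(profile$gaps))
      sprintf("%s\t%d\t%d\tgap", profile$ref_id, profile$gaps$start,
              profile$gaps$end) else character(0), gaps_bed)
  }
  invisible(NULL)
}
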