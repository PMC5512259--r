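#' Scoring parameters for ungapped seed-and-extend alignment
#'
#' Match/mismatch rewards with Karlin--Altschul statistical parameters for
#' the E-value of an ungapped local alignment, E = K m n exp(-lambda S).
#' Defaults are the conventional ungapped DNA values for +1/-2 scoring
#' (lambda ~ 1.28, K ~ 0.46) with the classic word size 11.
#'
#' @param match match reward (> 0).
#' @param mismatch mismatch penalty (< 0).
#' @param lambda,k Karlin--Altschul scale and prefactor (> 0).
#' @param word_size exact-seed length (>= 7).
#' @param xdrop stop extension when the running score drops this far below
#'   its maximum.
#' @return A `scoring_params` list.
#' @export
scoring_params <- function(match = 1L, mismatch = -2L, lambda = 1.28,
                           k = 0.46, word_size = 11L, xdrop = 20L) {
  stopifnot(match > 0, mismatch < 0, lambda > 0, k > 0, word_size >= 7,
            xdrop > 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 lambda = lambda, k = k, word_size = as.integer(word_size),
                 xdrop = as.integer(xdrop)), class = "scoring_params")
}

#' Exact-word index over query sequences
#'
#' Enumerates every `word_size`-mer of the forward strand of each query
#' (words containing N excluded) with all its offsets. Reads are searched on
#' both strands against this forward index.
#'
#' @param queries [seq_records] or character vector.
#' @param word_size word length.
#' @return Named list: word -> data.frame(`query_id`, `offset` 0-based).
#' @export
build_word_index <- function(queries, word_size = 11L) {
  qs <- .seqs(queries)
  idx <- cpp_word_index(unname(qs), as.integer(word_size))
  lapply(idx, function(m) {
    data.frame(query_id = names(qs)[m[, "query"]], offset = m[, "offset"],
               stringsAsFactors = FALSE)
  })
}

#' Karlin--Altschul E-value
#'
#' @param score ungapped alignment score (>= 0).
#' @param m total query length (bases).
#' @param n total database length (bases).
#' @param params a [scoring_params].
#' @return `k * m * n * exp(-lambda * score)`; strictly decreasing in score,
#'   linear in `m` and `n`.
#' @export
evalue <- function(score, m, n, params = scoring_params()) {
  stopifnot(all(score >= 0), m >= 1, n >= 1)
  params$k * m * n * exp(-params$lambda * score)
}

#' Ungapped seed-and-extend alignment of reads against queries
#'
#' For each strand of each read, every word shared with a query is extended
#' ungapped in both directions under an x-drop rule; extensions from seeds on
#' the same (query, diagonal, strand) are merged and the maximal-scoring one
#' reported (leftmost on ties). E-values use m = total query bases and
#' n = total read bases.
#'
#' @param reads [seq_records] or character vector (the database searched).
#' @param queries [seq_records] or character vector.
#' @param params a [scoring_params].
#' @return data.frame of hits: `query_id`, `subject_id`, `strand`
#'   (orientation of the subject relative to the forward query), 0-based
#'   half-open `q_start`/`q_end`/`s_start`/`s_end` (subject coordinates
#'   always on its forward strand), `length`, `matches`, `identity`,
#'   `score`, `evalue`.
#' @export
seed_extend <- function(reads, queries, params = scoring_params()) {
  qs <- .seqs(queries)
  rs <- .seqs(reads)
  h <- cpp_seed_extend(unname(rs), unname(qs), params$word_size,
                       params$match, params$mismatch, params$xdrop)
  len <- h$q_end - h$q_start
  out <- data.frame(query_id = names(qs)[h$query],
                    subject_id = names(rs)[h$subject],
                    strand = h$strand,
                    q_start = h$q_start, q_end = h$q_end,
                    s_start = h$s_start, s_end = h$s_end,
                    length = len, matches = h$matches,
                    identity = ifelse(len > 0, h$matches / len, 0),
                    score = h$score,
                    stringsAsFactors = FALSE)
  out$evalue <- evalue(pmax(out$score, 0), sum(nchar(qs)),
                       max(1, sum(nchar(rs))), params)
  out
}

#' Recruit reads matching query sequences
#'
#' A read is recruited iff at least one ungapped hit on either strand has
#' E-value at or below `e_max` (m = total query bases, n = total read bases
#' in the library). With `mate_rescue` (the default), recruiting either mate
#' of a pair recruits both; pair membership is taken from a shared id prefix
#' before a trailing `/1` / `/2`.
#'
#' @param queries [seq_records] of query sequences (non-empty).
#' @param reads a [seq_records] table, or a list with elements `r1`/`r2`
#'   as produced by [simulate_dna_reads].
#' @param params a [scoring_params].
#' @param e_max E-value threshold (default 1e-20).
#' @param mate_rescue logical.
#' @return `list(recruited, hits, best_score)`: recruited read ids, the
#'   passing hits, and a named vector of each recruited read's best passing
#'   score (rescued mates inherit their mate's score).
#' @export
recruit_reads <- function(queries, reads, params = scoring_params(),
                          e_max = 1e-20, mate_rescue = TRUE) {
  qs <- .seqs(queries)
  if (!length(qs)) stop("empty query set")
  stopifnot(e_max > 0)
  recs <- .flatten_reads(reads)
  if (!nrow(recs))
    return(list(recruited = character(), hits = NULL,
                best_score = numeric()))
  hits <- seed_extend(recs, queries, params)
  hits <- hits[hits$evalue <= e_max, , drop = FALSE]
  if (!nrow(hits))
    return(list(recruited = character(), hits = hits,
                best_score = numeric()))
  best <- tapply(hits$score, hits$subject_id, max)
  recruited <- names(best)
  best <- stats::setNames(as.numeric(best), recruited)
  if (mate_rescue && length(recruited)) {
    key <- sub("/[12]$", "", recs$id)
    hot <- key %in% sub("/[12]$", "", recruited)
    rescued <- setdiff(recs$id[hot], recruited)
    if (length(rescued)) {
      mate_best <- tapply(best, sub("/[12]$", "", names(best)), max)
      best <- c(best, stats::setNames(
        as.numeric(mate_best[sub("/[12]$", "", rescued)]), rescued))
      recruited <- c(recruited, rescued)
    }
  }
  ord <- match(intersect(recs$id, recruited), names(best))
  list(recruited = names(best)[ord], hits = hits,
       best_score = best[ord])
}

.flatten_reads <- function(reads) {
  if (is.list(reads) && !is.data.frame(reads) &&
      all(c("r1", "r2") %in% names(reads))) {
    out <- rbind(reads$r1[, c("id", "seq")], reads$r2[, c("id", "seq")])
    return(seq_records(out$id, out$seq))
  }
  if (inherits(reads, "seq_records") || is.data.frame(reads)) return(reads)
  s <- .seqs(reads)
  seq_records(names(s), unname(s))
}

#' Export alignment hits as BLAST outfmt6-like TSV
#'
#' Coordinates are converted to 1-based inclusive; on the minus strand the
#' subject start/end are swapped, per BLAST tabular convention.
#'
#' @param hits data.frame from [seed_extend] / [recruit_reads].
#' @param path output path.
#' @export
write_hits_tsv <- function(hits, path) {
  sstart <- ifelse(hits$strand == "-", hits$s_end, hits$s_start + 1L)
  send <- ifelse(hits$strand == "-", hits$s_start + 1L, hits$s_end)
  df <- data.frame(qseqid = hits$query_id, sseqid = hits$subject_id,
                   pident = round(100 * hits$identity, 2),
                   length = hits$length,
                   qstart = hits$q_start + 1L, qend = hits$q_end,
                   sstart = sstart, send = send,
                   evalue = signif(hits$evalue, 3), score = hits$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
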