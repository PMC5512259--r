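#' Map small-RNA reads with at most one mismatch
#'
#' Exhaustive placement of each read on both strands of every reference at
#' Hamming distance at most `max_mismatch` (N never matches). Placements
#' with the minimum mismatch count are "best"; by default one best placement
#' per read is reported, chosen uniformly at random among ties under `seed`
#' (emulating a short-read mapper's single-report default); `all_best = TRUE`
#' returns every best placement, for exhaustive cross-checks.
#'
#' @param reads [seq_records]; read lengths must lie in [15, 40].
#' @param refs [seq_records] of target references (non-empty).
#' @param max_mismatch maximum Hamming distance (default 1).
#' @param seed tie-breaking seed.
#' @param all_best report all best placements instead of one.
#' @return data.frame of placements: `read_id`, `ref_id`, `pos` (0-based
#'   leftmost on the reference forward strand), `strand` (`+` read equals
#'   the reference substring, `-` read equals its reverse complement),
#'   `length`, `mismatches`, `seq` (the read as sequenced). Unmapped reads
#'   are omitted.
#' @export
map_small_rna <- function(reads, refs, max_mismatch = 1L, seed = 1L,
                          all_best = FALSE) {
  rf <- .seqs(refs)
  if (!length(rf)) stop("empty reference set")
  rs <- .seqs(reads)
  lens <- nchar(rs)
  if (length(lens) && (min(lens) < 15 || max(lens) > 40))
    stop("read lengths must lie in [15, 40] nt")
  m <- cpp_map_hamming(unname(rs), unname(rf), as.integer(max_mismatch))
  if (!nrow(m)) return(.empty_placements())
  if (!all_best) {
    pick <- with_seed(seed, {
      unlist(lapply(split(seq_len(nrow(m)), m$read), function(ix) {
        if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
      }), use.names = FALSE)
    })
    m <- m[sort(pick), , drop = FALSE]
  }
  data.frame(read_id = names(rs)[m$read], ref_id = names(rf)[m$ref],
             pos = m$pos, strand = m$strand,
             length = nchar(rs)[m$read], mismatches = m$mismatches,
             seq = unname(rs)[m$read], stringsAsFactors = FALSE)
}

.empty_placements <- function() {
  data.frame(read_id = character(), ref_id = character(), pos = integer(),
             strand = character(), length = integer(), mismatches = integer(),
             seq = character(), stringsAsFactors = FALSE)
}

#' Strand-resolved small-RNA profile of one reference
#'
#' Computes per-position coverage by strand, read-length histograms
#' (18--35 nt window; reads outside are counted as filtered) by strand, the
#' positional nucleotide-frequency matrix of reads of `length_class`
#' (each read's own 5'->3' sequence; position 1 is the 5' base), and the
#' summary statistics used for locus classification: the antisense fraction,
#' the modal length, and the first-position U(T) frequency among antisense
#' reads of the modal class.
#'
#' @param placements data.frame from [map_small_rna]; all rows must be on
#'   `ref`.
#' @param ref a single-record [seq_records] (or named sequence).
#' @param length_class read length for the nucleotide-frequency matrix
#'   (default 28); `NULL` uses the modal length.
#' @return A `small_rna_profile` list: `ref_id`, `length`, `depth_fwd`,
#'   `depth_rev`, `size_hist_fwd`, `size_hist_rev`, `ntfreq`, `n_mapped`,
#'   `n_filtered`, `antisense_fraction`, `modal_length`, `u1_freq`,
#'   `length_class`.
#' @export
small_rna_profile <- function(placements, ref, length_class = 28L) {
  rf <- .seqs(ref)
  stopifnot(length(rf) == 1L)
  rid <- names(rf)
  L <- nchar(rf)
  if (nrow(placements) && !all(placements$ref_id == rid))
    stop("placements reference a different sequence than ", rid)
  inw <- placements$length >= 18L & placements$length <= 35L
  n_filtered <- sum(!inw)
  p <- placements[inw, , drop = FALSE]
  n_mapped <- nrow(p)

  depth_of <- function(q) {
    d <- numeric(L + 1L)
    if (nrow(q)) {
      add <- tabulate(q$pos + 1L, nbins = L + 1L)
      sub <- tabulate(pmin(q$pos + q$length, L) + 1L, nbins = L + 1L)
      d <- cumsum(add - sub)
    }
    d[seq_len(L)]
  }
  hist_of <- function(q) {
    h <- tabulate(factor(q$length, levels = 18:35), nbins = 18L)
    stats::setNames(h, 18:35)
  }
  fwd <- p[p$strand == "+", , drop = FALSE]
  rev <- p[p$strand == "-", , drop = FALSE]

  if (is.null(length_class)) {
    tot0 <- hist_of(fwd) + hist_of(rev)
    length_class <- if (sum(tot0)) as.integer(names(tot0)[which.max(tot0)]) else 28L
  }
  length_class <- as.integer(length_class)
  cls <- p$seq[p$length == length_class]
  ntfreq <- matrix(0, nrow = 4L, ncol = length_class,
                   dimnames = list(c("A", "C", "G", "T"),
                                   seq_len(length_class)))
  if (length(cls)) {
    ch <- matrix(unlist(strsplit(cls, "", fixed = TRUE), use.names = FALSE),
                 nrow = length_class)
    for (j in seq_len(length_class)) {
      cnt <- table(factor(ch[j, ], levels = c("A", "C", "G", "T")))
      tot <- sum(cnt)
      if (tot > 0) ntfreq[, j] <- as.numeric(cnt) / tot
    }
  }
  size_f <- hist_of(fwd); size_r <- hist_of(rev)
  tot <- size_f + size_r
  modal <- if (sum(tot)) as.integer(names(tot)[which.max(tot)]) else NA_integer_
  anti_modal <- rev[rev$length %in% modal, , drop = FALSE]
  structure(list(
    ref_id = rid, length = L,
    depth_fwd = depth_of(fwd), depth_rev = depth_of(rev),
    size_hist_fwd = size_f, size_hist_rev = size_r,
    ntfreq = ntfreq, n_mapped = n_mapped, n_filtered = n_filtered,
    antisense_fraction = if (n_mapped) nrow(rev) / n_mapped else NA_real_,
    modal_length = modal,
    u1_freq = if (nrow(anti_modal)) mean(substr(anti_modal$seq, 1L, 1L) == "T")
              else NA_real_,
    length_class = length_class), class = "small_rna_profile")
}

#' @export
print.small_rna_profile <- function(x, ...) {
  cat(sprintf(
    "<small_rna_profile> %s: %d mapped (%d filtered); modal length %s nt; antisense %.3f; U1 %.3f\n",
    x$ref_id, x$n_mapped, x$n_filtered,
    ifelse(is.na(x$modal_length), "NA", x$modal_length),
    x$antisense_fraction, x$u1_freq))
  invisible(x)
}

#' Classification thresholds for small-RNA loci
#'
#' Operational cutoffs for the qualitative piRNA/siRNA criteria: a
#' primary-piRNA-like locus has its modal mapped length in 27--29 nt, is
#' predominantly antisense, and shows a 5'-U bias; an siRNA peak is a
#' substantial fraction of exactly 21-nt reads.
#'
#' @param min_reads minimum mapped reads for any call (default 100).
#' @param antisense_min minimum antisense fraction (default 0.8).
#' @param u1_min minimum first-position U frequency (default 0.4).
#' @param sirna_min minimum fraction of 21-nt reads (default 0.2).
#' @return A `classify_thresholds` list.
#' @export
classify_thresholds <- function(min_reads = 100L, antisense_min = 0.8,
                                u1_min = 0.4, sirna_min = 0.2) {
  structure(list(min_reads = as.integer(min_reads),
                 antisense_min = antisense_min, u1_min = u1_min,
                 sirna_min = sirna_min), class = "classify_thresholds")
}

#' Classify a locus from its small-RNA profile
#'
#' `primary_pirna_like` requires modal length in 27--29 nt, antisense
#' fraction at or above `antisense_min`, and first-position U frequency at
#' or above `u1_min`. `sirna_peak` requires the fraction of mapped reads of
#' exactly 21 nt to reach `sirna_min`. Profiles with fewer than `min_reads`
#' mapped reads are reported as `insufficient_data` with both booleans NA.
#' `secondary_peak_length` is the modal length among mapped reads below the
#' piRNA band (18--23 nt; NA when none exist) — the length of any
#' non-piRNA peak, siRNA-sized or otherwise.
#'
#' @param profile a [small_rna_profile].
#' @param thresholds a [classify_thresholds].
#' @return A `locus_classification` list with `status`,
#'   `primary_pirna_like`, `sirna_peak`, `secondary_peak_length`, the
#'   evidence, and the thresholds used.
#' @export
classify_locus <- function(profile, thresholds = classify_thresholds()) {
  stopifnot(inherits(profile, "small_rna_profile"))
  tot <- profile$size_hist_fwd + profile$size_hist_rev
  frac21 <- if (profile$n_mapped) unname(tot["21"]) / profile$n_mapped else NA_real_
  sub <- tot[as.integer(names(tot)) <= 23L]
  sec <- if (sum(sub) > 0) as.integer(names(sub)[which.max(sub)]) else NA_integer_
  ev <- list(n_mapped = profile$n_mapped,
             modal_length = profile$modal_length,
             antisense_fraction = profile$antisense_fraction,
             u1_freq = profile$u1_freq, size21_fraction = frac21)
  if (profile$n_mapped < thresholds$min_reads) {
    return(structure(list(ref_id = profile$ref_id,
                          status = "insufficient_data",
                          primary_pirna_like = NA, sirna_peak = NA,
                          secondary_peak_length = NA_integer_,
                          evidence = ev, thresholds = unclass(thresholds)),
                     class = "locus_classification"))
  }
  pir <- !is.na(profile$modal_length) &&
    profile$modal_length >= 27L && profile$modal_length <= 29L &&
    !is.na(profile$antisense_fraction) &&
    profile$antisense_fraction >= thresholds$antisense_min &&
    !is.na(profile$u1_freq) && profile$u1_freq >= thresholds$u1_min
  structure(list(ref_id = profile$ref_id, status = "classified",
                 primary_pirna_like = pir,
                 sirna_peak = !is.na(frac21) && frac21 >= thresholds$sirna_min,
                 secondary_peak_length = sec,
                 evidence = ev, thresholds = unclass(thresholds)),
            class = "locus_classification")
}

#' Ping-pong 5'--5' overlap signature
#'
#' Counts opposite-strand placement pairs by the inclusive span between
#' their 5' ends (bin k = a k-nt overlap), over bins 1--20, and computes the
#' z-score of the 10-nt bin against the remaining bins — the classic
#' secondary-piRNA (ping-pong) diagnostic. Primary-piRNA-only loci, with all
#' reads on one strand, have an all-zero histogram and an undefined z10.
#'
#' @param placements data.frame from [map_small_rna] (>= 2 rows).
#' @return `list(overlap_hist, z10, z10_defined)`.
#' @export
ping_pong_signature <- function(placements) {
  if (nrow(placements) < 2L) stop("need at least 2 placements")
  counts <- stats::setNames(numeric(20L), 1:20)
  for (rid in unique(placements$ref_id)) {
    p <- placements[placements$ref_id == rid, , drop = FALSE]
    plus5 <- p$pos[p$strand == "+"]
    minus5 <- p$pos[p$strand == "-"] + p$length[p$strand == "-"] - 1L
    if (!length(plus5) || !length(minus5)) next
    off <- max(0L, min(plus5, minus5))
    np <- tabulate(plus5 - off + 1L, nbins = max(plus5, minus5) - off + 1L)
    nm <- tabulate(minus5 - off + 1L, nbins = max(plus5, minus5) - off + 1L)
    for (k in 1:20) {
      if (length(np) < k) next
      i <- seq_len(length(np) - k + 1L)
      counts[k] <- counts[k] + sum(np[i] * nm[i + k - 1L])
    }
  }
  others <- counts[-10L]
  sdo <- stats::sd(others)
  z10 <- if (is.na(sdo) || sdo == 0) NA_real_ else
    (counts[[10L]] - mean(others)) / sdo
  list(overlap_hist = counts, z10 = z10, z10_defined = !is.na(z10))
}
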