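#' Read a FASTA file
#'
#' Strict multi-line FASTA reader. Sequences are uppercased on read; any
#' character outside \{A,C,G,T,N\} is a parse error, as are headerless files,
#' headers with empty sequences, and duplicated ids. The id is the first
#' whitespace-delimited token after `>`.
#'
#' @param path path to an existing FASTA file.
#' @return A [seq_records] data.frame without qualities.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- sub("\r$", "", readLines(path))
  blank <- grepl("^[ \t]*$", lines)
  if (all(blank)) stop("parse error in ", path, ": no records")
  first <- which(!blank)[1]
  if (!startsWith(lines[first], ">"))
    stop("parse error in ", path, " at line ", first,
         ": expected '>' header before sequence data")
  is_hdr <- startsWith(lines, ">")
  grp <- cumsum(is_hdr)
  hdr_lines <- which(is_hdr)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[is_hdr]))
  if (any(!nzchar(ids)))
    stop("parse error in ", path, " at line ",
         hdr_lines[which(!nzchar(ids))[1]], ": empty header id")
  keep <- !is_hdr & !blank
  n_seq_lines <- tabulate(grp[keep], nbins = length(ids))
  if (any(n_seq_lines == 0))
    stop("parse error in ", path, " at line ",
         hdr_lines[which(n_seq_lines == 0)[1]], ": record '",
         ids[which(n_seq_lines == 0)[1]], "' has an empty sequence")
  seqs <- vapply(split(lines[keep], factor(grp[keep], levels = seq_along(ids))),
                 paste, collapse = "", FUN.VALUE = character(1))
  seqs <- toupper(gsub("[ \t]", "", seqs))
  if (anyDuplicated(ids))
    stop("parse error in ", path, ": duplicated id '",
         ids[duplicated(ids)][1], "'")
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("parse error in ", path, ": record '", ids[i],
         "' contains invalid character '",
         substr(seqs[i], bad[i], bad[i]), "'")
  }
  seq_records(ids, unname(seqs))
}

#' Write records to FASTA
#'
#' @param records a [seq_records] table (qualities, if any, are ignored).
#' @param path output path.
#' @param line_width wrap sequences at this many characters (default 70).
#' @export
write_fasta <- function(records, path, line_width = 70L) {
  stopifnot(line_width >= 1)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = line_width)
    writeLines(substring(s, starts, pmin(starts + line_width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' Four-line records only; a record count not divisible by four, a seq/qual
#' length mismatch, or a malformed `@`/`+` separator is a parse error.
#'
#' @param path path to an existing FASTQ file.
#' @return A [seq_records] data.frame with integer Phred qualities.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- sub("\r$", "", readLines(path))
  if (length(lines) %% 4L != 0L)
    stop("parse error in ", path, ": truncated record (line count ",
         length(lines), " is not a multiple of 4)")
  n <- length(lines) %/% 4L
  if (n == 0L) return(seq_records(character(), character(), list()))
  at <- seq(1L, by = 4L, length.out = n)
  if (!all(startsWith(lines[at], "@")))
    stop("parse error in ", path, " at line ",
         at[which(!startsWith(lines[at], "@"))[1]], ": expected '@' header")
  if (!all(startsWith(lines[at + 2L], "+")))
    stop("parse error in ", path, " at line ",
         at[which(!startsWith(lines[at + 2L], "+"))[1]],
         ": expected '+' separator")
  ids <- sub("\\s.*$", "", sub("^@", "", lines[at]))
  seqs <- toupper(lines[at + 1L])
  quals <- lines[at + 3L]
  mism <- nchar(seqs) != nchar(quals)
  if (any(mism))
    stop("parse error in ", path, " at line ", at[which(mism)[1]] + 3L,
         ": quality string length differs from sequence length")
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0))
    stop("parse error in ", path, ": record '", ids[which(bad > 0)[1]],
         "' contains an invalid sequence character")
  seq_records(ids, seqs, qual = lapply(quals, phred_decode))
}

#' Write records to FASTQ (Phred+33)
#'
#' @param records a [seq_records] table; every record must carry qualities.
#' @param path output path.
#' @export
write_fastq <- function(records, path) {
  has_q <- vapply(records$qual, Negate(is.null), logical(1))
  if (nrow(records) && !all(has_q))
    stop("write_fastq requires per-base qualities on every record")
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(records)) {
    out <- character(4L * nrow(records))
    out[seq(1L, by = 4L, length.out = nrow(records))] <- paste0("@", records$id)
    out[seq(2L, by = 4L, length.out = nrow(records))] <- records$seq
    out[seq(3L, by = 4L, length.out = nrow(records))] <- "+"
    out[seq(4L, by = 4L, length.out = nrow(records))] <-
      vapply(records$qual, phred_encode, character(1))
    writeLines(out, con)
  }
  invisible(path)
}

#' Phred+33 decode/encode
#'
#' @param x a quality string (decode) or an integer vector of Phred scores
#'   (encode).
#' @return Integer scores, or the encoded string.
#' @export
phred_decode <- function(x) {
  q <- utf8ToInt(x) - 33L
  if (any(q < 0L)) stop("quality character below Phred+33 '!'")
  q
}

#' @rdname phred_decode
#' @export
phred_encode <- function(x) intToUtf8(as.integer(x) + 33L)

#' Adaptor and quality trimming
#'
#' Configuration for [trim_reads]. `min_phred` is the running-sum quality
#' threshold (the pipeline default is 20, the conventional cutoff for
#' "acceptably" base-called Illumina data); `adapter`, when set, is removed
#' from the leftmost position where its prefix matches the read with at most
#' one mismatch (minimum match 8 nt, or the whole adaptor if shorter);
#' `min_len` discards reads left shorter after trimming.
#'
#' @param min_phred integer quality threshold, >= 0.
#' @param adapter optional adaptor sequence; `NULL` disables adaptor trimming
#'   (no default exists: adaptors are a property of the library prep).
#' @param min_len minimum retained read length, >= 1.
#' @return A `trim_config` list.
#' @export
trim_config <- function(min_phred = 20L, adapter = NULL, min_len = 18L) {
  stopifnot(min_phred >= 0, min_len >= 1)
  if (!is.null(adapter)) {
    adapter <- toupper(adapter)
    if (grepl("[^ACGT]", adapter)) stop("adapter must be over {A,C,G,T}")
  }
  structure(list(min_phred = as.integer(min_phred), adapter = adapter,
                 min_len = as.integer(min_len)), class = "trim_config")
}

# leftmost adaptor-prefix occurrence with <=1 mismatch; returns 0-based cut
# position or -1 when absent. Minimum match length 8 (or full adaptor).
.adapter_cut <- function(seq_raw, ad_raw, min_match) {
  L <- length(seq_raw); la <- length(ad_raw)
  for (p in seq_len(L)) {
    m <- min(la, L - p + 1L)
    if (m < min_match) break
    mm <- sum(seq_raw[p:(p + m - 1L)] != ad_raw[1:m])
    if (mm <= 1L) return(p - 1L)
  }
  -1L
}

# BWA-style 3' running-sum trim: cut the suffix of length k* maximizing
# sum(min_phred - q) over the suffix; no cut when every suffix sum <= 0.
# Ties take the smallest cut.
.qual_keep_len <- function(q, min_phred) {
  s <- cumsum(min_phred - rev(q))
  k <- which.max(s)
  if (s[k] > 0) length(q) - k else length(q)
}

#' Trim reads by adaptor and 3' quality
#'
#' Applies, in order: (1) adaptor removal at the leftmost exact-or-1-mismatch
#' occurrence of the adaptor prefix (minimum 8 nt of match, or the full
#' adaptor if shorter); (2) BWA-style 3' quality trimming — the suffix
#' maximizing the running sum of `min_phred - q` is removed when that maximum
#' is positive. Reads shorter than `min_len` afterwards are discarded; input
#' order is preserved.
#'
#' @param records a [seq_records] table with qualities on every record.
#' @param cfg a [trim_config].
#' @return The trimmed [seq_records]; attribute `n_discarded` counts dropped
#'   reads.
#' @export
trim_reads <- function(records, cfg = trim_config()) {
  stopifnot(inherits(cfg, "trim_config"))
  has_q <- vapply(records$qual, Negate(is.null), logical(1))
  if (nrow(records) && !all(has_q))
    stop("trim_reads requires per-base qualities on every record")
  ad_raw <- if (!is.null(cfg$adapter)) charToRaw(cfg$adapter)
  min_match <- if (!is.null(cfg$adapter)) min(8L, length(ad_raw))
  keep_id <- character(0); keep_seq <- character(0); keep_qual <- list()
  for (i in seq_len(nrow(records))) {
    s <- records$seq[i]; q <- records$qual[[i]]
    if (!is.null(ad_raw)) {
      cut <- .adapter_cut(charToRaw(s), ad_raw, min_match)
      if (cut >= 0L) {
        s <- substr(s, 1L, cut)
        q <- q[seq_len(cut)]
      }
    }
    if (nchar(s) > 0L) {
      kl <- .qual_keep_len(q, cfg$min_phred)
      s <- substr(s, 1L, kl)
      q <- q[seq_len(kl)]
    }
    if (nchar(s) >= cfg$min_len) {
      keep_id <- c(keep_id, records$id[i])
      keep_seq <- c(keep_seq, s)
      keep_qual[[length(keep_qual) + 1L]] <- q
    }
  }
  out <- seq_records(keep_id, keep_seq, keep_qual)
  attr(out, "n_discarded") <- nrow(records) - nrow(out)
  out
}

#' Write placements as minimal SAM
#'
#' Emits a header (`@HD VN:1.6`, one `@SQ` per reference) and one alignment
#' line per placement with the 11 mandatory fields: MAPQ 255, CIGAR
#' `<len>M` (the internal mappers are ungapped), `*` quality. Reverse-strand
#' placements set FLAG 16 and store the reverse complement of the read
#' sequence, per SAM convention; rows with `NA` ref set FLAG 4 (unmapped).
#'
#' @param placements data.frame with columns `read_id`, `ref_id`, `pos`
#'   (0-based leftmost), `strand` (`+`/`-`), `seq` (read as sequenced).
#' @param ref_lengths named integer vector of reference lengths.
#' @param path output path.
#' @export
write_sam_lite <- function(placements, ref_lengths, path) {
  stopifnot(!is.null(names(ref_lengths)))
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  body <- character(0)
  if (!is.null(placements) && nrow(placements)) {
    mapped <- !is.na(placements$ref_id)
    len <- nchar(placements$seq)
    if (any(mapped)) {
      over <- placements$pos[mapped] + len[mapped] >
        ref_lengths[placements$ref_id[mapped]] |
        placements$pos[mapped] < 0
      if (any(over))
        stop("placement outside reference bounds: read ",
             placements$read_id[mapped][which(over)[1]])
    }
    flag <- ifelse(!mapped, 4L, ifelse(placements$strand == "-", 16L, 0L))
    seqf <- ifelse(!is.na(placements$strand) & placements$strand == "-" & mapped,
                   revcomp(placements$seq), placements$seq)
    body <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*",
                    placements$read_id, flag,
                    ifelse(mapped, placements$ref_id, "*"),
                    ifelse(mapped, placements$pos + 1L, 0L),
                    ifelse(mapped, sprintf("%dM", len), "*"),
                    seqf)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
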