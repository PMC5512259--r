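#' Sequence record tables
#'
#' The atom of all I/O in this package is a *sequence record*: an identifier,
#' a nucleotide sequence over \{A,C,G,T,N\}, and optionally per-base Phred
#' quality scores. Collections of records are stored as a plain `data.frame`
#' with columns `id` (character), `seq` (character) and `qual` (a list column
#' of integer vectors, or `NULL` entries when no qualities exist), carrying
#' class `seq_records`.
#'
#' @param id character vector of unique identifiers.
#' @param seq character vector of sequences (uppercase A/C/G/T/N).
#' @param qual optional list of integer Phred score vectors, one per record,
#'   each the same length as its sequence; or a single integer to assign that
#'   constant quality to every base.
#' @return A `seq_records` data.frame.
#' @examples
#' seq_records("r1", "ACGT", qual = 40L)
#' @export
seq_records <- function(id, seq, qual = NULL) {
  id <- as.character(id)
  seq <- as.character(seq)
  if (length(id) != length(seq)) stop("id and seq must have equal length")
  if (anyDuplicated(id)) stop("record ids must be unique")
  if (is.null(qual)) {
    qual <- vector("list", length(seq))
  } else if (is.numeric(qual) && length(qual) == 1L) {
    qual <- lapply(nchar(seq), function(n) rep.int(as.integer(qual), n))
  } else {
    if (!is.list(qual) || length(qual) != length(seq))
      stop("qual must be a list with one integer vector per record")
    ok <- vapply(seq_along(qual), function(i) {
      is.null(qual[[i]]) || length(qual[[i]]) == nchar(seq[[i]])
    }, logical(1))
    if (!all(ok)) stop("qual length must equal seq length for every record")
    qual <- lapply(qual, function(q) if (is.null(q)) NULL else as.integer(q))
  }
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad))
    stop("sequence contains characters outside {A,C,G,T,N}: record ",
         id[which(bad)[1]])
  out <- data.frame(id = id, seq = seq, stringsAsFactors = FALSE)
  out$qual <- qual
  class(out) <- c("seq_records", "data.frame")
  out
}

#' @export
print.seq_records <- function(x, ...) {
  cat(sprintf("<seq_records> %d record(s); lengths %s; qualities: %s\n",
              nrow(x),
              if (nrow(x)) paste(range(nchar(x$seq)), collapse = "-") else "-",
              if (nrow(x) && !is.null(x$qual[[1]])) "yes" else "no"))
  invisible(x)
}

#' Reverse-complement nucleotide sequences
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements; N maps to N.
#' @export
revcomp <- function(x) cpp_revcomp(toupper(as.character(x)))

# uniform helper: coerce seq_records / character to a character seq vector
.seqs <- function(x) {
  if (inherits(x, "seq_records") || (is.data.frame(x) && "seq" %in% names(x))) {
    stats::setNames(x$seq, x$id)
  } else if (is.character(x)) {
    if (is.null(names(x))) stats::setNames(x, paste0("seq", seq_along(x))) else x
  } else stop("expected seq_records or a character vector of sequences")
}

# scoped RNG: runs code under set.seed(seed), restoring global RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# i.i.d. random sequence at a target GC content
random_seq <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# substitute n_sub random positions with a different base
mutate_seq <- function(seq, n_sub) {
  if (n_sub <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(ch), min(n_sub, length(ch)))
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}
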