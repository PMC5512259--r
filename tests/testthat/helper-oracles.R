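# Independent brute-force oracles. These deliberately share no code with the
# package implementation: plain loops, their own reverse complement, their
# own scoring.

orc_rc <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rand_records <- function(n, len_range = c(20, 200), with_qual = FALSE,
                         alphabet = c("A", "C", "G", "T")) {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  seqs <- vapply(lens, function(l)
    paste(sample(alphabet, l, replace = TRUE), collapse = ""), character(1))
  qual <- if (with_qual) lapply(lens, function(l)
    sample(0:41, l, replace = TRUE)) else NULL
  seq_records(sprintf("rec%04d", seq_len(n)), seqs, qual)
}

# point mutations at an exact count
mutate_n <- function(seq, n_sub) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in sample.int(length(ch), n_sub)) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

# -- trimming oracle: explicit per-position loops ---------------------------
orc_trim <- function(records, cfg) {
  ids <- character(0); seqs <- character(0); quals <- list()
  for (i in seq_len(nrow(records))) {
    s <- strsplit(records$seq[i], "", fixed = TRUE)[[1]]
    q <- records$qual[[i]]
    if (!is.null(cfg$adapter)) {
      a <- strsplit(cfg$adapter, "", fixed = TRUE)[[1]]
      need <- min(8, length(a))
      for (p in seq_along(s)) {
        m <- min(length(a), length(s) - p + 1)
        if (m < need) break
        if (sum(s[p:(p + m - 1)] != a[1:m]) <= 1) {
          s <- s[seq_len(p - 1)]
          q <- q[seq_len(p - 1)]
          break
        }
      }
    }
    if (length(s)) {
      best <- 0; bestk <- 0
      for (k in seq_along(q)) {
        v <- sum(cfg$min_phred - q[(length(q) - k + 1):length(q)])
        if (v > best) { best <- v; bestk <- k }
      }
      if (bestk > 0) {
        s <- s[seq_len(length(s) - bestk)]
        q <- q[seq_len(length(q) - bestk)]
      }
    }
    if (length(s) >= cfg$min_len) {
      ids <- c(ids, records$id[i])
      seqs <- c(seqs, paste(s, collapse = ""))
      quals[[length(quals) + 1]] <- q
    }
  }
  list(id = ids, seq = seqs, qual = quals)
}

# -- best ungapped local alignment score over all offsets (Kadane) ----------
orc_best_ungapped <- function(read, queries, match = 1, mismatch = -2) {
  best <- 0
  for (qs in queries) {
    B <- strsplit(qs, "", fixed = TRUE)[[1]]
    for (s in c(read, orc_rc(read))) {
      A <- strsplit(s, "", fixed = TRUE)[[1]]
      la <- length(A); lb <- length(B)
      for (off in (-(la - 1)):(lb - 1)) {
        i1 <- max(1, 1 - off); i2 <- min(la, lb - off)
        if (i2 < i1) next
        a <- A[i1:i2]; b <- B[(i1 + off):(i2 + off)]
        v <- ifelse(a == b & a != "N" & b != "N", match, mismatch)
        cs <- cumsum(v)
        # best-scoring contiguous segment on this diagonal (Kadane)
        best <- max(best, cs - cummin(c(0, cs[-length(cs)])))
      }
    }
  }
  best
}

# -- sliding-window Hamming scan: all minimum-mismatch placements -----------
orc_hamming_map <- function(read, refs, max_mm = 1L) {
  nraw <- charToRaw("N")
  scan1 <- function(rd, R) {
    l <- length(rd)
    if (length(R) < l) return(NULL)
    mm <- integer(0); pos <- integer(0)
    for (p in 0:(length(R) - l)) {
      w <- R[(p + 1):(p + l)]
      d <- sum(w != rd | w == nraw | rd == nraw)
      if (d <= max_mm) { mm <- c(mm, d); pos <- c(pos, p) }
    }
    if (!length(pos)) NULL else data.frame(pos = pos, mm = mm)
  }
  out <- NULL
  for (ri in seq_along(refs)) {
    R <- charToRaw(refs[[ri]])
    for (strand in c("+", "-")) {
      rd <- charToRaw(if (strand == "+") read else orc_rc(read))
      hits <- scan1(rd, R)
      if (!is.null(hits)) {
        hits$ref <- ri; hits$strand <- strand
        out <- rbind(out, hits)
      }
    }
  }
  if (is.null(out)) return(NULL)
  out[out$mm == min(out$mm), c("ref", "pos", "strand", "mm")]
}

# -- brute-force pileup -----------------------------------------------------
orc_pileup <- function(pos, len, strand, L) {
  fwd <- numeric(L); rev_ <- numeric(L)
  for (i in seq_along(pos)) {
    ix <- (pos[i] + 1):min(pos[i] + len[i], L)
    if (strand[i] == "+") fwd[ix] <- fwd[ix] + 1 else rev_[ix] <- rev_[ix] + 1
  }
  list(fwd = fwd, rev = rev_)
}

# a small integrated world shared by several suites
make_world <- function(seed = 3, genome_len = 30000,
                       plans = NULL, eve_len = 1500, n_eves = 3,
                       coverage = 30) {
  set.seed(seed + 1000)
  eves <- seq_records(paste0("EVE", seq_len(n_eves)),
                      vapply(seq_len(n_eves), function(i) rand_seq(eve_len),
                             character(1)))
  if (is.null(plans)) {
    plans <- list(integration_plan("EVE1", "full", sirna = TRUE))
  }
  g <- make_repeat_rich_genome(genome_spec(length = genome_len, seed = seed))
  ig <- integrate_eves(g, eves, plans, seed = seed + 1)
  glen <- nchar(ig$genome$seq[1])
  dna <- simulate_dna_reads(ig$genome,
                            dna_read_model(n_pairs = ceiling(coverage * glen / 302),
                                           seed = seed + 2))
  list(eves = eves, base = g, ig = ig, dna = dna)
}

locus_span <- function(truth_row) {
  fl <- truth_row$flank_intervals[[1]]
  adj <- fl[fl$copy == 0, ]
  c(min(adj$start), max(adj$end))
}

extract_locus <- function(ig, i, id = "locus") {
  sp <- locus_span(ig$truth[i, ])
  seq_records(id, substr(ig$genome$seq[1], sp[1] + 1, sp[2]))
}
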