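test_that("one-mismatch mapping handles exact, tolerated, excluded reads", {
  set.seed(71)
  ref <- seq_records("R", rand_seq(500))
  read <- substr(ref$seq, 11, 38)  # refs[0][10:38] in 0-based terms
  pl <- map_small_rna(seq_records("a", read), ref)
  expect_equal(pl$pos, 10)
  expect_equal(pl$strand, "+")
  expect_equal(pl$mismatches, 0)

  pl1 <- map_small_rna(seq_records("b", mutate_n(read, 1)), ref)
  expect_equal(pl1$pos, 10)
  expect_equal(pl1$mismatches, 1)

  pl2 <- map_small_rna(seq_records("c", mutate_n(read, 3)), ref)
  expect_equal(nrow(pl2), 0)  # beyond the mismatch allowance

  # antisense: read equal to the reverse complement of a window
  plr <- map_small_rna(seq_records("d", orc_rc(read)), ref)
  expect_equal(plr$pos, 10)
  expect_equal(plr$strand, "-")

  # N never matches
  nn <- paste0("N", substr(read, 2, 28))
  pln <- map_small_rna(seq_records("e", nn), ref)
  expect_equal(pln$mismatches, 1)

  expect_error(map_small_rna(seq_records("a", read),
                             seq_records(character(), character())),
               "empty reference")
  expect_error(map_small_rna(seq_records("a", rand_seq(50)), ref),
               "\\[15, 40\\]")
})

test_that("the mapper agrees with an exhaustive Hamming scan", {
  set.seed(72)
  refs <- seq_records(c("r1", "r2"), c(rand_seq(1200), rand_seq(800)))
  reads <- character(300)
  for (i in seq_along(reads)) {
    l <- sample(18:35, 1)
    if (i %% 3 == 0) {
      reads[i] <- rand_seq(l)  # mostly unmappable
    } else {
      src <- sample(1:2, 1)
      p <- sample(nchar(refs$seq[src]) - l, 1)
      r <- substr(refs$seq[src], p + 1, p + l)
      r <- mutate_n(r, sample(0:2, 1))
      if (runif(1) < 0.5) r <- orc_rc(r)
      reads[i] <- r
    }
  }
  got <- map_small_rna(seq_records(sprintf("q%03d", seq_along(reads)), reads),
                       refs, all_best = TRUE)
  for (i in seq_along(reads)) {
    want <- orc_hamming_map(reads[i], refs$seq, 1)
    sub <- got[got$read_id == sprintf("q%03d", i), , drop = FALSE]
    if (is.null(want)) {
      expect_equal(nrow(sub), 0, label = paste("read", i))
    } else {
      expect_setequal(paste(sub$ref_id, sub$pos, sub$strand, sub$mismatches),
                      paste(refs$id[want$ref], want$pos, want$strand,
                            want$mm))
    }
  }
  # single-report mode returns exactly one of the best placements per read
  one <- map_small_rna(seq_records(sprintf("q%03d", seq_along(reads)), reads),
                       refs, seed = 9)
  expect_true(all(table(one$read_id) == 1))
  expect_true(all(paste(one$read_id, one$ref_id, one$pos, one$strand) %in%
                  paste(got$read_id, got$ref_id, got$pos, got$strand)))
})

test_that("profiles keep strand-resolved books that sum to n_mapped", {
  set.seed(77)
  ref <- seq_records("L", rand_seq(1000))
  empty <- small_rna_profile(map_small_rna(seq_records("x", strrep("A", 20)),
                                           ref)[0, ], ref)
  expect_equal(empty$n_mapped, 0)
  expect_true(all(empty$depth_fwd == 0) && all(empty$depth_rev == 0))
  expect_true(all(colSums(empty$ntfreq) == 0))

  # a single 28-nt antisense placement starting with T
  read <- orc_rc(substr(ref$seq, 1, 28))
  read <- paste0("T", substr(read, 2, 28))
  pl <- map_small_rna(seq_records("a", read), ref)
  expect_equal(pl$strand, "-")
  prof <- small_rna_profile(pl, ref, length_class = 28)
  expect_equal(prof$antisense_fraction, 1.0)
  expect_equal(prof$u1_freq, 1.0)
  expect_equal(prof$ntfreq["T", 1], 1.0)
  expect_equal(sum(prof$depth_rev), 28)
  expect_equal(sum(prof$depth_fwd), 0)

  # synthetic library: conservation and column sums
  w <- make_world(seed = 73, genome_len = 20000)
  sr <- simulate_small_rna(w$ig, w$ig$truth,
                           small_rna_model(n_reads = 4000, seed = 7))
  locus <- extract_locus(w$ig, 1)
  plc <- map_small_rna(sr, locus)
  p <- small_rna_profile(plc, locus)
  expect_equal(sum(p$size_hist_fwd) + sum(p$size_hist_rev), p$n_mapped)
  cs <- colSums(p$ntfreq)
  expect_true(all(abs(cs[cs > 0] - 1) < 1e-9))

  # strand relabeling: reverse-complementing the reference swaps the books
  locus_rc <- seq_records(locus$id, revcomp(locus$seq))
  prc <- small_rna_profile(map_small_rna(sr, locus_rc), locus_rc)
  expect_equal(prc$depth_fwd, base::rev(p$depth_rev))
  expect_equal(prc$depth_rev, base::rev(p$depth_fwd))
  expect_equal(prc$size_hist_fwd, p$size_hist_rev)

  expect_error(small_rna_profile(data.frame(ref_id = "other", pos = 1,
                                            strand = "+", length = 20,
                                            seq = "A"), ref),
               "different sequence")
})

test_that("locus classification applies its stated rules", {
  mkprof <- function(n, len, strand, first = "T") {
    ref <- seq_records("L", rand_seq(2000))
    pos <- sample(0:(2000 - len), n, replace = TRUE)
    seqs <- vapply(pos, function(p) {
      s <- substr(ref$seq, p + 1, p + len)
      if (strand == "-") s <- orc_rc(s)
      paste0(first, substr(s, 2, len))
    }, character(1))
    pl <- data.frame(read_id = paste0("r", seq_len(n)), ref_id = "L",
                     pos = pos, strand = strand, length = len,
                     mismatches = 0L, seq = seqs, stringsAsFactors = FALSE)
    small_rna_profile(pl, ref)
  }
  set.seed(74)
  c1 <- classify_locus(mkprof(500, 28, "-"))
  expect_true(c1$primary_pirna_like)
  expect_false(c1$sirna_peak)

  c2 <- classify_locus(mkprof(500, 21, "+"))
  expect_false(c2$primary_pirna_like)
  expect_true(c2$sirna_peak)
  expect_equal(c2$secondary_peak_length, 21L)

  c3 <- classify_locus(mkprof(99, 28, "-"))
  expect_equal(c3$status, "insufficient_data")
  expect_true(is.na(c3$primary_pirna_like))
})

test_that("ping-pong signature counts 5'-5' overlaps and flags one-strand data", {
  mono <- data.frame(read_id = c("a", "b"), ref_id = "L", pos = c(0, 40),
                     strand = "-", length = 28L, mismatches = 0L,
                     seq = "x", stringsAsFactors = FALSE)
  pp0 <- ping_pong_signature(mono)
  expect_true(all(pp0$overlap_hist == 0))
  expect_false(pp0$z10_defined)

  # plus 5' at 100, minus 5' at 109 -> a 10-nt overlap
  pair <- data.frame(read_id = c("p", "m"), ref_id = "L",
                     pos = c(100L, 82L), strand = c("+", "-"),
                     length = 28L, mismatches = 0L, seq = "x",
                     stringsAsFactors = FALSE)
  pp1 <- ping_pong_signature(pair)
  expect_equal(unname(pp1$overlap_hist[["10"]]), 1)
  expect_equal(sum(pp1$overlap_hist), 1)

  # planted ping-pong pairs at rate 0.5 give a strong z10; a balanced
  # random library shows no consistent signal across seeds
  null_z <- numeric(10)
  for (s in 1:10) {
    set.seed(100 + s)
    n <- 300
    pos <- sample(30:1800, n, replace = TRUE)
    plus <- data.frame(read_id = paste0("p", 1:n), ref_id = "L", pos = pos,
                       strand = "+", length = 28L, mismatches = 0L,
                       seq = "x", stringsAsFactors = FALSE)
    partner <- pos[1:(n / 2)] + 9 - 27  # minus-read pos so its 5' is pos+9
    minus <- data.frame(read_id = paste0("m", 1:(n / 2)), ref_id = "L",
                        pos = partner, strand = "-", length = 28L,
                        mismatches = 0L, seq = "x", stringsAsFactors = FALSE)
    planted <- ping_pong_signature(rbind(plus, minus))
    expect_gt(planted$z10, 5)

    rnd <- data.frame(read_id = paste0("r", 1:n), ref_id = "L",
                      pos = sample(0:1800, n, replace = TRUE),
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      length = 28L, mismatches = 0L, seq = "x",
                      stringsAsFactors = FALSE)
    null <- ping_pong_signature(rnd)
    null_z[s] <- null$z10
    expect_lt(abs(null$z10), 3.5)  # no per-seed signal
  }
  expect_lt(abs(mean(null_z)), 1)  # and none in aggregate
})

test_that("synthetic defaults are recovered as a primary-piRNA locus", {
  w <- make_world(seed = 75, genome_len = 20000,
                  plans = list(integration_plan("EVE1", "full")))
  sr <- simulate_small_rna(w$ig, w$ig$truth,
                           small_rna_model(n_reads = 10000, seed = 3))
  locus <- extract_locus(w$ig, 1)
  pl <- map_small_rna(sr, locus)
  prof <- small_rna_profile(pl, locus)
  expect_equal(prof$antisense_fraction, 1.0)  # exact under defaults
  u <- prof$u1_freq
  expect_lt(abs(u - 0.7), 3 * sqrt(0.7 * 0.3 / prof$n_mapped))
  expect_true(classify_locus(prof)$primary_pirna_like)
})
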