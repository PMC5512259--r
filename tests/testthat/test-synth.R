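test_that("repeat-rich genome generation meets its coverage contract", {
  sp0 <- genome_spec(length = 20000, repeat_fraction = 0, seed = 4)
  g0 <- make_repeat_rich_genome(sp0)
  expect_equal(nrow(g0$repeats), 0)
  expect_equal(nchar(g0$genome$seq), 20000)

  sp <- genome_spec(length = 100000, repeat_fraction = 0.6, seed = 1)
  g <- make_repeat_rich_genome(sp)
  expect_equal(nchar(g$genome$seq), 100000)
  cov <- sum(g$repeats$end - g$repeats$start)
  expect_gte(cov / 100000, 0.6)
  # annotated copies are non-overlapping
  o <- order(g$repeats$start)
  expect_true(all(g$repeats$start[o][-1] >= g$repeats$end[o][-nrow(g$repeats)]))
  # each copy diverges at most ~5% from something; spot-check determinism
  g2 <- make_repeat_rich_genome(sp)
  expect_identical(g$genome$seq, g2$genome$seq)
  expect_identical(g$repeats, g2$repeats)

  expect_error(make_repeat_rich_genome(
    genome_spec(length = 1000, repeat_fraction = 0.9, repeat_unit_len = 400,
                n_repeat_families = 1, repeat_copy_range = c(1, 1), seed = 1)),
    "achieved")
})

test_that("integration conserves length and records exact coordinates", {
  set.seed(21)
  eves <- seq_records(c("EVE1", "EVE2"),
                     c(rand_seq(1200), rand_seq(900)))
  g <- make_repeat_rich_genome(genome_spec(length = 20000, seed = 7))

  out0 <- integrate_eves(g, eves, list(), seed = 1)
  expect_identical(out0$genome$seq, g$genome$seq)
  expect_equal(nrow(out0$truth), 0)

  plans <- list(
    integration_plan("EVE1", "full", flank_copy_number = 3L),
    integration_plan("EVE2", "five_prime_truncated", truncation_len = 200),
    integration_plan("EVE1", "fusion", partner_eve_id = "EVE2",
                     strand = "-"),
    integration_plan("EVE2", "interrupted", insert_len = 500))
  out <- integrate_eves(g, eves, plans, seed = 9)
  grow <- nchar(out$genome$seq) - nchar(g$genome$seq)
  expected <- (1200 + 2000 + 2 * 2 * 1000) +   # full + flanks + 2 extra copies
    (700 + 2000) +                             # truncated
    (600 + 900 + 2000) +                       # fusion: half of EVE1 + EVE2
    (450 + 500 + 450 + 2000)                   # interrupted
  expect_equal(grow, expected)

  tr <- out$truth
  expect_equal(tr$mode,
               c("full", "five_prime_truncated", "fusion", "interrupted"))
  # extracting each truth interval reproduces the planned insert exactly
  g2 <- out$genome$seq
  ext <- function(i) substr(g2, tr$start[i] + 1, tr$end[i])
  expect_identical(ext(1), eves$seq[1])
  expect_identical(ext(2), substr(eves$seq[2], 201, 900))
  fus <- paste0(substr(eves$seq[1], 1, 600), eves$seq[2])
  expect_identical(ext(3), revcomp(fus))  # minus-strand insertion
  # interrupted: the element-internal segments tile the truth interval and
  # the EVE parts match the reference halves
  seg <- tr$segments[[4]]
  expect_equal(seg$start[1], tr$start[4])
  expect_equal(seg$end[nrow(seg)], tr$end[4])
  expect_identical(substr(g2, seg$start[1] + 1, seg$end[1]),
                   substr(eves$seq[2], 1, 450))
  expect_identical(substr(g2, seg$start[3] + 1, seg$end[3]),
                   substr(eves$seq[2], 451, 900))
  # flank intervals extract to consistent copies
  fl <- tr$flank_intervals[[1]]
  left <- fl[fl$side == "left", ]
  pieces <- vapply(seq_len(nrow(left)), function(j)
    substr(g2, left$start[j] + 1, left$end[j]), character(1))
  expect_true(all(pieces == pieces[1]))
  expect_equal(nrow(left), 3)  # copy 0 + 2 extra
})

test_that("DNA read simulation matches its fragment model", {
  set.seed(22)
  gen <- seq_records("g", rand_seq(10000))

  empty <- simulate_dna_reads(gen, dna_read_model(n_pairs = 0))
  expect_equal(nrow(empty$r1), 0)

  m <- dna_read_model(n_pairs = 1000, error_rate = 0, seed = 5)
  rr <- simulate_dna_reads(gen, m)
  both <- paste0(gen$seq, "NNN", revcomp(gen$seq))
  expect_true(all(vapply(rr$r1$seq, function(s)
    grepl(s, both, fixed = TRUE), logical(1))))
  expect_true(all(vapply(rr$r2$seq, function(s)
    grepl(s, both, fixed = TRUE), logical(1))))
  expect_true(all(nchar(rr$r1$seq) == 151))
  # r2 is the reverse complement of the fragment 3' end
  tr <- rr$truth
  frag1 <- substr(gen$seq, tr$start[1] + 1, tr$start[1] + tr$frag_len[1])
  if (tr$strand[1] == "-") frag1 <- revcomp(frag1)
  expect_identical(rr$r2$seq[1], substr(revcomp(frag1), 1, 151))

  m2 <- dna_read_model(n_pairs = 10000, error_rate = 0, seed = 6)
  rr2 <- simulate_dna_reads(gen, m2)
  se <- 20 / sqrt(10000)
  expect_lt(abs(mean(rr2$truth$frag_len) - 200), 3 * se + 0.5)
})

test_that("small-RNA simulation reproduces the signature it models", {
  w <- make_world(seed = 31, genome_len = 20000)
  model <- small_rna_model(n_reads = 10000, seed = 8)
  sr <- simulate_small_rna(w$ig, w$ig$truth, model)
  expect_equal(nrow(sr), 10000)
  tr <- attr(sr, "truth")

  # defaults: all piRNA-class (sirna share) or siRNA on the flagged locus
  expect_true(all(tr$class %in% c("piRNA", "siRNA")))
  pir <- tr$class == "piRNA"
  # antisense_fraction 1: every piRNA read is on the strand opposite the
  # element sense (here '+'), i.e. genomic '-'
  expect_true(all(tr$genomic_strand[pir] == "-"))
  # u1: first-base T frequency within the 99.7% binomial interval of 0.7
  tfreq <- mean(substr(sr$seq[pir], 1, 1) == "T")
  expect_lt(abs(tfreq - 0.7), 3 * sqrt(0.7 * 0.3 / sum(pir)))
  # length histogram matches the model distribution (chi-square GOF)
  probs <- pirna_length_probs(model)
  obs <- table(factor(tr$len[pir], levels = names(probs)))
  expect_gt(stats::chisq.test(obs, p = probs)$p.value, 0.001)
  # siRNA class: exactly 21 nt, restricted to flagged flanks
  si <- tr$class == "siRNA"
  expect_true(all(tr$len[si] == 21))
  fl <- w$ig$truth$flank_intervals[[1]]
  adj <- fl[fl$copy == 0, ]
  inside <- vapply(which(si), function(i)
    any(tr$start[i] >= adj$start & tr$start[i] + 21 <= adj$end), logical(1))
  expect_true(all(inside))

  expect_equal(nrow(simulate_small_rna(w$ig, w$ig$truth,
                                       small_rna_model(n_reads = 0))), 0)
})

test_that("generators are pure functions of their seeds", {
  sp <- genome_spec(length = 15000, seed = 42)
  expect_identical(make_repeat_rich_genome(sp),
                   make_repeat_rich_genome(sp))
  w1 <- make_world(seed = 5, genome_len = 15000)
  w2 <- make_world(seed = 5, genome_len = 15000)
  expect_identical(w1$ig$genome$seq, w2$ig$genome$seq)
  expect_identical(w1$dna$r1$seq, w2$dna$r1$seq)
  m <- small_rna_model(n_reads = 500, seed = 3)
  expect_identical(simulate_small_rna(w1$ig, w1$ig$truth, m)$seq,
                   simulate_small_rna(w2$ig, w2$ig$truth, m)$seq)
})
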