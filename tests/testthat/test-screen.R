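test_that("an iteration of the loop composes its four steps", {
  set.seed(91)
  w <- make_world(seed = 92, genome_len = 15000, coverage = 25)

  # unrelated reads recruit nothing and assemble nothing
  rnd <- seq_records(paste0("n", 1:500),
                     vapply(1:500, function(i) rand_seq(151), character(1)))
  out0 <- run_iteration(w$eves, rnd)
  expect_equal(nrow(out0), 0)
  expect_equal(attr(out0, "log")$n_recruited, 0)

  out1 <- run_iteration(w$eves, w$dna)
  expect_gt(nrow(out1), 0)
  expect_true(all(out1$length > 400))
  lg <- attr(out1, "log")
  expect_false(lg$capped)
  expect_lte(lg$max_evalue_recruited, 1e-20)
  # a contig covers most of the planted element at high identity
  h <- seed_extend(out1$seq, w$eves[1, ])
  expect_gte(max(h$matches), 0.95 * 1500 * 0.99)

  out2 <- run_iteration(w$eves, w$dna)
  expect_identical(out1, out2)  # deterministic pipeline of deterministic stages

  # the recruit cap keeps the highest-scoring reads and is logged
  cfg_cap <- screen_config(recruit_cap = 50L)
  outc <- run_iteration(w$eves, w$dna, cfg_cap)
  expect_true(attr(outc, "log")$capped)
  expect_equal(attr(outc, "log")$n_recruited, 50)
})

test_that("contig dedupe removes identical, reverse-complement and near copies", {
  set.seed(93)
  a <- rand_seq(900)
  two <- data.frame(id = c("c1", "c2"), seq = c(a, a),
                    stringsAsFactors = FALSE)
  expect_equal(nrow(dedupe_contigs(two)), 1)

  rc2 <- data.frame(id = c("c1", "c2"), seq = c(a, orc_rc(a)),
                    stringsAsFactors = FALSE)
  expect_equal(nrow(dedupe_contigs(rc2)), 1)

  # planted 96%-identity pairs vs an independent pairwise-alignment dedupe
  base_seqs <- vapply(1:10, function(i) rand_seq(sample(500:900, 1)),
                      character(1))
  dups <- vapply(base_seqs[1:5], function(s)
    mutate_n(s, round(0.04 * nchar(s))), character(1))
  pool <- c(base_seqs, dups)
  contigs <- data.frame(id = paste0("c", seq_along(pool)), seq = pool,
                        stringsAsFactors = FALSE)
  got <- dedupe_contigs(contigs, identity = 0.95, coverage = 0.90)

  orc_dedupe <- function(seqs, identity = 0.95, coverage = 0.90) {
    ord <- order(-nchar(seqs), seqs)
    kept <- character(0)
    for (s in seqs[ord]) {
      dup <- FALSE
      for (r in kept) {
        for (cand in c(s, orc_rc(s))) {
          aln <- Biostrings::pairwiseAlignment(
            cand, r, type = "local",
            substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
              match = 1, mismatch = -2),
            gapOpening = 5, gapExtension = 2)
          cov <- Biostrings::nchar(Biostrings::pattern(aln)) / nchar(s)
          if (cov >= coverage &&
              Biostrings::pid(aln) / 100 >= identity) dup <- TRUE
        }
      }
      if (!dup) kept <- c(kept, s)
    }
    kept
  }
  expect_setequal(got$seq, orc_dedupe(pool))
})

test_that("contig annotation segments EVE and flanking sequence", {
  set.seed(94)
  eves <- seq_records(c("E1", "E2"), c(rand_seq(1000), rand_seq(800)))

  a1 <- annotate_contig(c(ctg = eves$seq[1]), eves)
  expect_equal(nrow(a1$segments), 1)
  expect_equal(a1$segments$label, "E1")
  expect_equal(a1$segments$identity, 1.0)
  expect_equal(c(a1$segments$start, a1$segments$end), c(0, 1000))

  ctg <- paste0(rand_seq(300), eves$seq[1], rand_seq(300))
  a2 <- annotate_contig(c(ctg = ctg), eves)
  expect_equal(a2$segments$label, c("non-EVE", "E1", "non-EVE"))
  expect_lt(abs(a2$segments$start[2] - 300), 10)
  expect_lt(abs(a2$segments$end[2] - 1300), 10)
  # segments tile the contig without overlap
  expect_equal(a2$segments$start[-1], a2$segments$end[-nrow(a2$segments)])
  expect_equal(a2$segments$start[1], 0)
  expect_equal(a2$segments$end[nrow(a2$segments)], nchar(ctg))

  a3 <- annotate_contig(c(ctg = rand_seq(700)), eves)
  expect_equal(a3$segments$label, "non-EVE")

  # a fusion-structured contig gets two differently-labeled segments
  fus <- paste0(substr(eves$seq[1], 1, 500), eves$seq[2])
  a4 <- annotate_contig(c(ctg = fus), eves)
  lab <- a4$segments$label[a4$segments$label != "non-EVE"]
  expect_equal(lab, c("E1", "E2"))
})

test_that("the iterative screen walks outward and stops when saturated", {
  w <- make_world(seed = 95, genome_len = 20000, coverage = 30)
  cfg <- screen_config()
  scr <- iterative_screen(w$eves, w$dna, cfg)
  expect_gt(nrow(scr$contigs), 0)
  expect_true(all(scr$contigs$length > cfg$min_contig_len))
  expect_true(all(vapply(scr$log, function(l)
    is.na(l$max_evalue_recruited) || l$max_evalue_recruited <= cfg$e_max,
    logical(1))))

  # the best contig covers >=95% of the planted element and extends >=500 nt
  # into flanking sequence
  covers <- vapply(scr$annotations, function(a) {
    seg <- a$segments
    e <- seg[seg$label == "EVE1", , drop = FALSE]
    f <- seg[seg$label == "non-EVE", , drop = FALSE]
    length(e) && nrow(e) && max(e$end - e$start) >= 0.95 * 1500 &&
      nrow(f) > 0 && max(f$end - f$start) >= 500
  }, logical(1))
  expect_true(any(covers))

  # iteration provenance: first contigs appear at iteration 1, later ones
  # extend them
  expect_true(any(scr$contigs$iteration_found == 1) ||
                all(scr$contigs$iteration_found >= 1))

  # max_iterations 1 degenerates to one annotated iteration
  cfg1 <- screen_config(max_iterations = 1)
  scr1 <- iterative_screen(w$eves, w$dna, cfg1)
  it1 <- dedupe_contigs(run_iteration(w$eves, w$dna, cfg1),
                        cfg1$dedupe_identity, cfg1$dedupe_coverage)
  expect_setequal(scr1$contigs$seq, it1$seq)
})

test_that("recovered elements never shrink as iterations increase", {
  w <- make_world(seed = 96, genome_len = 20000, coverage = 30,
                  plans = list(
                    integration_plan("EVE1", "full"),
                    integration_plan("EVE2", "fusion",
                                     partner_eve_id = "EVE3")))
  recovered <- function(max_it) {
    scr <- iterative_screen(w$eves, w$dna,
                            screen_config(max_iterations = max_it))
    labs <- unlist(lapply(scr$annotations, function(a) a$segments$label))
    sort(unique(labs[labs != "non-EVE"]))
  }
  r1 <- recovered(1); r2 <- recovered(2); r3 <- recovered(3)
  expect_true(all(r1 %in% r2))
  expect_true(all(r2 %in% r3))
  # the fusion yields a contig carrying two different element labels
  scr <- iterative_screen(w$eves, w$dna, screen_config())
  multi <- vapply(scr$annotations, function(a) {
    lab <- unique(a$segments$label[a$segments$label != "non-EVE"])
    length(lab) >= 2
  }, logical(1))
  expect_true(any(multi))
})

test_that("presence calls reflect depth and continuity of coverage", {
  w <- make_world(seed = 97, genome_len = 15000, coverage = 30)
  other <- with_seed_helper <- NULL
  set.seed(98)
  absent_ref <- seq_records("ghost", rand_seq(1500))
  half_ref <- seq_records("half",
                          paste0(rand_seq(750),
                                 substr(w$eves$seq[1], 751, 1500)))
  pres <- call_presence(
    seq_records(c("EVE1", "ghost", "half"),
                c(w$eves$seq[1], absent_ref$seq, half_ref$seq)),
    w$dna)
  expect_equal(pres$call[pres$element_id == "EVE1"], "present")
  expect_equal(pres$call[pres$element_id == "ghost"], "absent")
  expect_equal(pres$call[pres$element_id == "half"], "partial")
  h <- pres[pres$element_id == "half", ]
  expect_lt(h$covered_fraction, 0.95)
  expect_gte(h$covered_fraction, 0.3)
})
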