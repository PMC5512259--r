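test_that("word index equals brute-force enumeration", {
  idx <- build_word_index(c(q = "ACGTACGT"), word_size = 4)
  expect_setequal(names(idx), c("ACGT", "CGTA", "GTAC", "TACG"))
  expect_equal(idx[["ACGT"]]$offset, c(0, 4))
  expect_equal(idx[["CGTA"]]$offset, 1)

  # query shorter than the word contributes nothing
  idx2 <- build_word_index(c(a = "ACG", b = "ACGTACGT"), word_size = 8)
  expect_equal(names(idx2), "ACGTACGT")

  # random set vs enumeration oracle (words with N excluded)
  set.seed(41)
  qs <- c(x = rand_seq(60), y = paste0(rand_seq(20), "N", rand_seq(20)))
  w <- 7
  idx3 <- build_word_index(qs, w)
  want <- list()
  for (qi in names(qs)) {
    s <- qs[[qi]]
    for (p in 0:(nchar(s) - w)) {
      word <- substr(s, p + 1, p + w)
      if (grepl("N", word)) next
      want[[word]] <- rbind(want[[word]],
                            data.frame(query_id = qi, offset = p))
    }
  }
  expect_setequal(names(idx3), names(want))
  for (word in names(want)) {
    expect_equal(idx3[[word]], want[[word]], ignore_attr = TRUE)
  }
})

test_that("E-value follows the Karlin-Altschul closed form", {
  p <- scoring_params()
  s1 <- log(p$k * 500 * 1e6) / p$lambda
  expect_equal(evalue(s1, 500, 1e6, p), 1.0)
  expect_equal(evalue(50, 500, 2e6, p), 2 * evalue(50, 500, 1e6, p))
  # independent log-space evaluation, 12 significant digits
  direct <- exp(log(0.46) + log(500) + log(1e6) - 1.28 * 50)
  expect_equal(evalue(50, 500, 1e6, scoring_params(lambda = 1.28, k = 0.46)),
               direct, tolerance = 1e-12)
  # strictly decreasing in score
  expect_true(all(diff(evalue(0:100, 500, 1e6, p)) < 0))
})

test_that("seed-and-extend recovers exact and mutated matches", {
  set.seed(42)
  q <- c(Q1 = rand_seq(1000))
  read <- substr(q[[1]], 301, 451)
  h <- seed_extend(c(r = read), q)
  h <- h[which.max(h$score), ]  # chance word hits may add low-score rows
  expect_equal(h$identity, 1.0)
  expect_equal(h$score, 151)
  expect_equal(h$q_start, 300)
  expect_equal(h$q_end, 451)
  expect_equal(h$strand, "+")

  # reverse-complemented read: same score, flipped strand (strand symmetry)
  h2 <- seed_extend(c(r = orc_rc(read)), q)
  h2 <- h2[which.max(h2$score), ]
  expect_equal(h2$score, h$score)
  expect_equal(h2$strand, "-")
  expect_equal(h2[c("q_start", "q_end")], h[c("q_start", "q_end")],
               ignore_attr = TRUE)

  # a read with no shared word yields nothing
  h3 <- seed_extend(c(r = strrep("AT", 40)), c(q = strrep("GC", 200)))
  expect_equal(nrow(h3), 0)
})

test_that("best reported score equals the brute-force ungapped optimum", {
  set.seed(43)
  queries <- c(A = rand_seq(800), B = rand_seq(600), C = rand_seq(500))
  reads <- character(100)
  for (i in seq_along(reads)) {
    src <- sample(names(queries), 1)
    l <- sample(60:151, 1)
    p <- sample(nchar(queries[[src]]) - l, 1)
    r <- substr(queries[[src]], p, p + l - 1)
    r <- mutate_n(r, rbinom(1, l, 0.01))
    if (runif(1) < 0.5) r <- orc_rc(r)
    reads[i] <- r
  }
  names(reads) <- sprintf("r%03d", seq_along(reads))
  h <- seed_extend(reads, queries)
  got_best <- tapply(h$score, h$subject_id, max)
  for (rn in names(reads)) {
    expect_equal(unname(got_best[[rn]]),
                 orc_best_ungapped(reads[[rn]], queries), label = rn)
  }
})

test_that("recruitment matches the combined aligner + E-value oracle", {
  set.seed(44)
  eve <- c(EVE = rand_seq(1500))
  # reads simulated from the EVE locus at 1% error pass; unrelated reads never
  reads <- character(500)
  from_eve <- logical(500)
  for (i in 1:500) {
    if (i <= 300) {
      p <- sample(1350, 1)
      r <- mutate_n(substr(eve[[1]], p, p + 150), rbinom(1, 151, 0.01))
      if (runif(1) < 0.5) r <- orc_rc(r)
      reads[i] <- r; from_eve[i] <- TRUE
    } else {
      reads[i] <- rand_seq(151)
    }
  }
  names(reads) <- sprintf("r%03d", 1:500)
  rec <- recruit_reads(seq_records(names(reads), reads),
                       reads = seq_records(names(reads), reads)[0, ],
                       e_max = 1)  # smoke the empty-read path
  expect_length(rec$recruited, 0)

  res <- recruit_reads(seq_records("EVE", eve[[1]]),
                       seq_records(names(reads), reads),
                       mate_rescue = FALSE)
  m <- 1500; n <- sum(nchar(reads))
  want <- names(reads)[vapply(reads, function(r)
    evalue(orc_best_ungapped(r, eve), m, n) <= 1e-20, logical(1))]
  expect_setequal(res$recruited, want)
  expect_true(all(res$hits$evalue <= 1e-20))
  # no unrelated read sneaks in; essentially every EVE read is recruited
  expect_true(all(res$recruited %in% names(reads)[from_eve]))
  expect_gt(length(res$recruited) / sum(from_eve), 0.97)

  # an exact 151-nt substring always passes the default threshold
  exact <- substr(eve[[1]], 11, 161)
  r1 <- recruit_reads(seq_records("EVE", eve[[1]]),
                      seq_records("x", exact))
  expect_equal(r1$recruited, "x")
  expect_true(all(r1$hits$evalue <= 1e-20))

  # unrelated random genome: empty recruitment at 1e-20
  set.seed(45)
  rnd <- vapply(1:2000, function(i) rand_seq(151), character(1))
  r0 <- recruit_reads(seq_records("EVE", eve[[1]]),
                      seq_records(paste0("n", 1:2000), rnd))
  expect_length(r0$recruited, 0)

  expect_error(recruit_reads(seq_records(character(), character()),
                             seq_records("x", exact)), "empty query")
})

test_that("recruitment is monotone in the E-value threshold and rescues mates", {
  set.seed(46)
  w <- make_world(seed = 51, genome_len = 15000, coverage = 15)
  strict <- recruit_reads(w$eves, w$dna, e_max = 1e-30)
  loose <- recruit_reads(w$eves, w$dna, e_max = 1e-10)
  expect_true(all(strict$recruited %in% loose$recruited))

  # every recruited read's mate is recruited too
  key <- sub("/[12]$", "", loose$recruited)
  expect_true(all(table(key) == 2))
  # without rescue, only reads with their own passing hit remain
  solo <- recruit_reads(w$eves, w$dna, mate_rescue = FALSE)
  expect_setequal(solo$recruited, unique(solo$hits$subject_id))
  expect_true(length(solo$recruited) <= length(loose$recruited))
})
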