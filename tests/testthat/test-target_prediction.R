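mk_site <- function(mirna, changes = list()) {
  site <- revcomp(mirna)
  L <- nchar(mirna)
  for (ch in changes) {
    k <- ch$pos
    j <- L - k + 1
    b <- substr(mirna, k, k)
    partner <- c(A = "U", C = "G", G = "C", U = "A")[b]
    wobble <- c(G = "U", U = "G")[b]
    repl <- if (identical(ch$kind, "GU")) unname(wobble) else
      setdiff(c("A", "C", "G", "U"), c(partner, wobble))[1]
    substr(site, j, j) <- repl
  }
  site
}

test_that("duplex scoring counts G:U as half a mismatch", {
  m <- "UUGACAGAAGAUAGAGAGCAC"
  d0 <- score_duplex(m, revcomp(m))
  expect_equal(d0$mismatch_score, 0)
  expect_equal(d0$energy_ratio, 100)
  expect_true(all(d0$pair_states == "match"))

  d1 <- score_duplex(m, mk_site(m, list(list(pos = 7, kind = "GU"))))
  expect_equal(d1$mismatch_score, 0.5)
  expect_equal(d1$pair_states[7], "GU")

  d2 <- score_duplex(m, mk_site(m, list(list(pos = 14), list(pos = 18),
                                        list(pos = 7, kind = "GU"))))
  expect_equal(d2$mismatch_score, 2.5)
  expect_error(score_duplex(m, "ACGU"), "length")
})

test_that("each rule triggers on its own violation pattern", {
  m <- "UUGACAGAAGAUAGAGAGCAC"
  expect_equal(apply_rules(score_duplex(m, revcomp(m))), character(0))

  d_iv <- score_duplex(m, mk_site(m, list(list(pos = 10))))
  expect_true("iv" %in% apply_rules(d_iv))

  d_ii <- score_duplex(m, mk_site(m, list(list(pos = 18), list(pos = 19),
                                          list(pos = 20))))
  expect_true("ii" %in% apply_rules(d_ii))

  d_i <- score_duplex(m, mk_site(m, lapply(c(13, 15, 17, 19, 21),
                                           function(p) list(pos = p))))
  expect_true("i" %in% apply_rules(d_i))

  d_iii <- score_duplex(m, mk_site(m, list(list(pos = 6))))
  expect_true("iii" %in% apply_rules(d_iii))
  # a wobble in 2-12 is tolerated by default but not in strict mode
  d_gu <- score_duplex(m, mk_site(m, list(list(pos = 7, kind = "GU"))))
  expect_false("iii" %in% apply_rules(d_gu))
  expect_true("iii" %in% apply_rules(d_gu, target_thresholds(strict_seed = TRUE)))

  # the energy-ratio floor is inclusive at 74
  d_b <- score_duplex(m, revcomp(m))
  d_b$energy_ratio <- 74
  expect_false("vi" %in% apply_rules(d_b))
  d_b$energy_ratio <- 73.9
  expect_true("vi" %in% apply_rules(d_b))
})

test_that("rule evaluation agrees with the plain-coded oracle on random duplexes", {
  set.seed(101)
  for (i in 1:500) {
    L <- sample(19:24, 1)
    states <- sample(c("match", "GU", "mismatch"), L, replace = TRUE,
                     prob = c(0.7, 0.15, 0.15))
    ratio <- runif(1, 40, 110)
    d <- structure(list(pair_states = states,
                        mismatch_score = sum(states == "mismatch") +
                          0.5 * sum(states == "GU"),
                        energy_ratio = ratio), class = "target_duplex")
    expect_setequal(apply_rules(d), oracle_rules(states, ratio))
  }
})

test_that("adding a mismatch never turns a failing duplex into a pass", {
  set.seed(111)
  for (i in 1:100) {
    L <- 21
    states <- sample(c("match", "GU", "mismatch"), L, replace = TRUE,
                     prob = c(0.8, 0.1, 0.1))
    ratio <- runif(1, 60, 100)
    d <- structure(list(pair_states = states,
                        mismatch_score = sum(states == "mismatch") +
                          0.5 * sum(states == "GU"),
                        energy_ratio = ratio), class = "target_duplex")
    pass1 <- length(apply_rules(d)) == 0
    k <- sample(which(states != "mismatch"), 1)
    states2 <- states; states2[k] <- "mismatch"
    d2 <- structure(list(pair_states = states2,
                         mismatch_score = sum(states2 == "mismatch") +
                           0.5 * sum(states2 == "GU"),
                         energy_ratio = ratio), class = "target_duplex")
    pass2 <- length(apply_rules(d2)) == 0
    expect_false(!pass1 && pass2)
  }
})

test_that("transcriptome scan reports planted sites at exact coordinates", {
  set.seed(121)
  m <- rand_rna(21)
  tx_seq <- rand_rna(1000)
  site <- revcomp(m)
  substr(tx_seq, 401, 421) <- site
  tx <- data.frame(id = "TX1", sequence = tx_seq)
  hits <- scan_transcriptome(c(mirX = m), tx)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 401)
  expect_equal(hits$end, 421)
  expect_equal(hits$mismatch_score, 0)
  expect_equal(hits$energy_ratio, 100)
  expect_equal(hits$cleavage_site, 401 + 21 - 10)

  # a rule-iv violating site is not reported
  tx2_seq <- rand_rna(1000)
  substr(tx2_seq, 301, 321) <- mk_site(m, list(list(pos = 10)))
  hits2 <- scan_transcriptome(c(mirX = m),
                              data.frame(id = "TX2", sequence = tx2_seq))
  expect_equal(nrow(hits2), 0)

  # spans always have miRNA length and stay on the transcript
  sim <- small_sim()
  mat <- sim$gh$truth$mature[startsWith(sim$gh$truth$type, "conforming")]
  txs <- simulate_transcriptome(sim$cfg, setNames(mat, paste0("m", seq_along(mat))))
  all_hits <- scan_transcriptome(setNames(mat, paste0("m", seq_along(mat))),
                                 txs$transcripts)
  lens <- nchar(mat)[match(all_hits$mirna_name, paste0("m", seq_along(mat)))]
  expect_equal(all_hits$end - all_hits$start + 1, lens)
  expect_true(all(all_hits$start >= 1))
  expect_true(all(all_hits$end <= sim$cfg$transcript_length))
})

test_that("scan count on a null transcript matches a window-by-window check", {
  set.seed(131)
  m <- rand_rna(21)
  tx_seq <- rand_rna(3000)
  hits <- scan_transcriptome(c(mir = m), data.frame(id = "T", sequence = tx_seq))
  brute <- 0
  for (s in 1:(3000 - 21 + 1)) {
    d <- score_duplex(m, substr(tx_seq, s, s + 20))
    if (length(oracle_rules(d$pair_states, d$energy_ratio)) == 0) brute <- brute + 1
  }
  expect_equal(nrow(hits), brute)
})

test_that("annotation joins count targets per category", {
  targets <- data.frame(mirna_name = c("a", "b"),
                        transcript_id = c("T1", "T2"))
  ann <- data.frame(transcript_id = c("T1", "T2", "T2", "T3"),
                    category = c("defense", "defense", "metabolism", "defense"))
  out <- annotate_targets(targets, ann)
  expect_equal(out$n_targets[out$category == "defense"], 2L)
  expect_equal(out$n_targets[out$category == "metabolism"], 1L)
})
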