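# a deterministic conforming precursor used across tests
make_test_hairpin <- function(seed = 13, arm_ext = c(8, 8), loop = 12) {
  set.seed(seed)
  mature <- rand_rna(21)
  arm <- paste0(rand_rna(arm_ext[1]), mature, rand_rna(arm_ext[2]))
  list(mature = mature,
       precursor = paste0(arm, rand_rna(loop), revcomp(arm)))
}

test_that("map_and_excise finds loci on both strands and excises two windows", {
  set.seed(14)
  tag <- rand_rna(21)
  genome <- data.frame(id = "chr1",
                       sequence = paste0(rand_rna(300), tag, rand_rna(300)))
  wins <- map_and_excise(tag, genome)
  expect_equal(nrow(wins), 2)
  expect_true(all(wins$strand == "+"))
  for (w in 1:2) {
    expect_equal(substr(wins$window[w], wins$tag_offset[w],
                        wins$tag_offset[w] + 20), tag)
  }

  genome_rc <- data.frame(id = "chr1", sequence = revcomp(genome$sequence))
  wins_rc <- map_and_excise(tag, genome_rc)
  expect_equal(nrow(wins_rc), 2)
  expect_true(all(wins_rc$strand == "-"))
  for (w in 1:2) {
    expect_equal(substr(wins_rc$window[w], wins_rc$tag_offset[w],
                        wins_rc$tag_offset[w] + 20), tag)
  }

  expect_equal(nrow(map_and_excise(rand_rna(25), genome)), 0)

  # a mature inside a planted hairpin: its star also maps (minus strand),
  # and some window contains the full precursor
  hp <- make_test_hairpin()
  genome_hp <- data.frame(
    id = "chr1",
    sequence = paste0(rand_rna(300), hp$precursor, rand_rna(300)))
  wins_hp <- map_and_excise(hp$mature, genome_hp)
  expect_gte(nrow(wins_hp), 2)
  expect_true(any(vapply(wins_hp$window, grepl, TRUE, pattern = hp$precursor,
                         fixed = TRUE)))
})

test_that("repeat-like tags beyond max_loci are skipped", {
  set.seed(15)
  tag <- rand_rna(21)
  genome <- data.frame(id = "chr1",
                       sequence = paste(rep(c(tag, rand_rna(50)), 4),
                                        collapse = ""))
  expect_message(out <- map_and_excise(tag, genome, max_loci = 2),
                 "repeat-like")
  expect_equal(nrow(out), 0)
})

test_that("a planted ideal hairpin is accepted with the right arm", {
  hp <- make_test_hairpin(seed = 23, arm_ext = c(10, 10), loop = 15)
  cand <- evaluate_candidate(hp$precursor, hp$mature)
  expect_true(cand$accepted)
  expect_equal(cand$arm, "5p")
  expect_true(all(cand$criteria))
  expect_lte(cand$mfe, -20)
  expect_equal(cand$mature_span, c(11, 31))
  expect_false(is.null(cand$star_span))
  # star is disjoint from the mature, on the other arm
  expect_true(cand$star_span[1] > cand$mature_span[2])

  # same hairpin with the mature on the 3p arm
  arm <- paste0(rand_rna(10), revcomp(hp$mature), rand_rna(10))
  prec3 <- paste0(arm, rand_rna(15), revcomp(arm))
  cand3 <- evaluate_candidate(prec3, hp$mature)
  expect_true(cand3$accepted)
  expect_equal(cand3$arm, "3p")

  expect_error(evaluate_candidate(hp$precursor, rand_rna(21)), "exactly once")
})

test_that("the MFE bound is inclusive at the threshold", {
  hp <- make_test_hairpin(seed = 29)
  cand <- evaluate_candidate(hp$precursor, hp$mature)
  at <- evaluate_candidate(hp$precursor, hp$mature,
                           thresholds = novel_thresholds(mfe_max = cand$mfe))
  expect_true(at$criteria[["v"]])
  above <- evaluate_candidate(hp$precursor, hp$mature,
                              thresholds = novel_thresholds(mfe_max = cand$mfe - 0.01))
  expect_false(above$criteria[["v"]])
  expect_true("v" %in% above$failed)
})

test_that("loop-straddling matures and bulged duplexes are rejected", {
  set.seed(33)
  mature <- rand_rna(21)
  arm5 <- paste0(rand_rna(12), substr(mature, 1, 10))
  prec_ii <- paste0(arm5, substr(mature, 11, 21), rand_rna(14), revcomp(arm5))
  cand_ii <- evaluate_candidate(prec_ii, mature)
  expect_false(cand_ii$accepted)
  expect_false(cand_ii$criteria[["ii"]])

  # 6 nt deleted opposite the mature: a large duplex bulge
  arm <- paste0(rand_rna(10), mature, rand_rna(10))
  star <- revcomp(arm)
  cut <- nchar(arm) - 10 - 14
  star_del <- paste0(substr(star, 1, cut - 1), substr(star, cut + 6, nchar(star)))
  cand_iv <- evaluate_candidate(paste0(arm, rand_rna(15), star_del), mature)
  expect_false(cand_iv$accepted)
  expect_false(cand_iv$criteria[["iv"]])
})

test_that("all spoiler hairpins from the generator are rejected, all failures reported", {
  sim <- small_sim()
  sp <- sim$gh$truth[!startsWith(sim$gh$truth$type, "conforming"), ]
  for (i in seq_len(nrow(sp))) {
    cand <- evaluate_candidate(sp$precursor[i], sp$mature[i])
    expect_false(cand$accepted, info = sp$type[i])
    expect_gt(length(cand$failed), 0)
    expect_setequal(cand$failed, names(cand$criteria)[!cand$criteria])
    lab <- sub("spoiler_", "", sp$type[i])
    if (lab %in% c("iv", "v")) {
      expect_false(cand$criteria[[lab]], info = sp$type[i])
    }
  }
})

test_that("novel expression counts terminal variants but not internal edits", {
  hp <- make_test_hairpin(seed = 37, arm_ext = c(10, 10))
  m <- hp$mature
  shifted <- substr(hp$precursor, 11 + 2, 11 + 20 + 2)  # 2 nt 3' shift
  internal <- m
  substr(internal, 11, 11) <- setdiff(c("A", "C", "G", "U"),
                                      substr(m, 11, 11))[1]
  tags <- small_rna_tags(c(m, shifted, internal), c(1448, 20, 7))
  expect_equal(quantify_novel(m, small_rna_tags(m, 1448)), 1448)
  expect_equal(quantify_novel(m, tags), 1468)
  cand <- evaluate_candidate(hp$precursor, m)
  expect_equal(quantify_novel(cand, tags), 1468)
})

test_that("discovery over the synthetic genome recovers planted truth", {
  sim <- small_sim()
  cl <- clean_library(sim$lib$reads)
  tags <- filter_ncrna(cl$tags, sim$lib$exclusion_set)
  hits <- assign_known(tags, sim$db$db)
  un <- unassigned_tags(tags, hits)
  nov <- discover_novel(un, sim$gh$genome)
  conf <- sim$gh$truth[startsWith(sim$gh$truth$type, "conforming"), ]
  expect_true(all(conf$mature %in% nov$table$sequence))
  spoil <- sim$gh$truth$mature[!startsWith(sim$gh$truth$type, "conforming")]
  expect_false(any(spoil %in% nov$table$sequence))
  # arms recovered as planted
  m <- match(conf$mature, nov$table$sequence)
  expect_equal(nov$table$arm[m], conf$arm)
  # names follow the <prefix>-miRN<k>-<arm> convention in count order
  expect_true(all(grepl("^col-miRN[0-9]+-[35]p$", nov$table$name)))
  expect_true(!is.unsorted(rev(tags$count[match(nov$table$sequence, tags$sequence)])))
})

test_that("a pair-poor null genome yields no accepted candidates", {
  set.seed(99)
  null_genome <- data.frame(id = "chr1", sequence = rand_rna(30000))
  tags <- small_rna_tags(vapply(1:15, function(i) {
    s <- sample.int(30000 - 21, 1)
    substr(null_genome$sequence, s, s + 20)
  }, ""), rep(5, 15))
  nov <- discover_novel(tags, null_genome)
  expect_equal(nrow(nov$table), 0)
})
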