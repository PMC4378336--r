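test_that("miRBase-style names parse into species, family and suffix", {
  p <- parse_mirna_name(c("ath-miR157a", "gma-miR396b-3p", "osa-MIR171b",
                          "weird_header"))
  expect_equal(p$species, c("ath", "gma", "osa", NA))
  expect_equal(p$family, c("miR157", "miR396", "miR171", NA))
  expect_equal(p$suffix, c("a", "b-3p", "b", NA))
  expect_equal(p$ok, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("ncRNA filtering removes exactly the planted fragments", {
  excl <- data.frame(id = c("rRNA:r1", "tRNA:t1"),
                     sequence = c(rand_rna(120), rand_rna(90)))
  set.seed(17)
  frag <- vapply(1:20, function(i) {
    s <- sample.int(100, 1)
    substr(excl$sequence[1], s, s + 20)
  }, "")
  mir <- vapply(1:20, function(i) rand_rna(21), "")
  tags <- small_rna_tags(unique(c(frag, mir)),
                         seq_along(unique(c(frag, mir))) + 10)
  kept <- filter_ncrna(tags, excl)
  expect_setequal(kept$sequence, setdiff(unique(c(frag, mir)), frag))
  removed <- attr(kept, "removed")
  expect_equal(removed$class, "rRNA")
  expect_equal(removed$tags, length(unique(frag)))

  # exact mode keeps substrings, removes only equal sequences
  t2 <- small_rna_tags(c(substr(excl$sequence[2], 1, 21), excl$sequence[2]),
                       c(4, 2))
  kept2 <- filter_ncrna(t2, excl, mode = "exact")
  expect_equal(kept2$sequence, substr(excl$sequence[2], 1, 21))
})

test_that("known assignment finds identical and near-identical homologs", {
  db <- data.frame(id = c("ath-miR156a", "ath-miR157a", "osa-miR171b"),
                   sequence = c("UGACAGAAGAGAGUGAGCAC",
                                "UUGACAGAAGAUAGAGAGCAC",
                                "UGAUUGAGCCGUGCCAAUAUC"))
  tags <- small_rna_tags(c("UGACAGAAGAGAGUGAGCAC", rand_rna(21)), c(100, 5))
  hits <- assign_known(tags, db)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$db_name, "ath-miR156a")
  expect_equal(hits$assigned_name, "col-miR156a")
  expect_equal(c(hits$matches, hits$mismatches, hits$gaps), c(20L, 0L, 0L))
  expect_equal(hits$family, "miR156")

  un <- unassigned_tags(tags, hits)
  expect_equal(nrow(un), 1)

  far <- small_rna_tags("CCCCCCCCCCGGGGGGGGGGG", 3)
  expect_equal(nrow(assign_known(far, db)), 0)

  db_bad <- rbind(db, data.frame(id = "not_a_mirna", sequence = rand_rna(21)))
  expect_warning(assign_known(tags, db_bad), "unparseable")
})

test_that("planted matures mutated within the budget recover their family", {
  sim <- small_sim()
  cl <- clean_library(sim$lib$reads)
  tags <- filter_ncrna(cl$tags, sim$lib$exclusion_set)
  hits <- assign_known(tags, sim$db$db)
  known_truth <- sim$lib$truth[sim$lib$truth$label == "clean" &
                                 grepl("^known:", sim$lib$truth$source), ]
  known_truth <- known_truth[!duplicated(known_truth$insert), ]
  m <- match(as_rna(known_truth$insert), hits$sequence)
  planted_fam <- sub("^known:", "", known_truth$source)
  expect_true(all(!is.na(m)))
  expect_equal(hits$family[m], planted_fam)
})

test_that("family grouping picks the most expressed representative and re-counts", {
  db <- data.frame(id = c("ath-miR157a", "ath-miR156a"),
                   sequence = c("UUGACAGAAGAUAGAGAGCAC",
                                "UGACAGAAGAGAGUGAGCAC"))
  tags <- small_rna_tags(c("UUGACAGAAGAUAGAGAGCAC", "UGACAGAAGAGAGUGAGCAC"),
                         c(5531609, 1724997))
  hits <- assign_known(tags, db)
  fam <- group_and_quantify(hits, tags)
  expect_equal(nrow(fam), 1)
  expect_equal(fam$family, "miR156")
  expect_equal(fam$representative, "col-miR157a")
  expect_equal(fam$representative_count, 5531609)
  # brute-force expression oracle: sum counts of member tags within the
  # budget of the representative
  rep_seq <- fam$representative_sequence
  manual <- sum(tags$count[vapply(tags$sequence, function(s) {
    !is.null(align_with_budget(s, rep_seq, 3))
  }, logical(1))])
  expect_equal(fam$expression, manual)

  single <- assign_known(small_rna_tags("UGAUUGAGCCGUGCCAAUAUC", 558),
                         data.frame(id = "osa-miR171b",
                                    sequence = "UGAUUGAGCCGUGCCAAUAUC"))
  fam1 <- group_and_quantify(single,
                             small_rna_tags("UGAUUGAGCCGUGCCAAUAUC", 558))
  expect_equal(fam1$expression, 558)
})

test_that("family expressions never exceed the total tag count", {
  sim <- small_sim()
  cl <- clean_library(sim$lib$reads)
  tags <- filter_ncrna(cl$tags, sim$lib$exclusion_set)
  hits <- assign_known(tags, sim$db$db)
  fam <- group_and_quantify(hits, tags)
  expect_lte(sum(fam$expression), sum(tags$count))
})

test_that("conservation classification applies the 9-species threshold", {
  presence <- matrix(FALSE, 12, 3,
                     dimnames = list(paste0("sp", 1:12),
                                     c("miR156", "miR397", "miR9999")))
  presence[1:9, "miR156"] <- TRUE
  presence[1:8, "miR397"] <- TRUE
  fams <- data.frame(family = c("miR156", "miR397", "miR777"))
  out <- classify_conservation(fams, presence)
  expect_equal(out$conservation,
               c("conserved", "nonconserved_defined", "nonconserved_undefined"))
  expect_equal(out$species_presence, c(9L, 8L, 0L))

  # presence tables built from a database reflect its species spread
  sim <- small_sim()
  pres <- build_presence_table(sim$db$db)
  expect_equal(unname(colSums(pres)[sim$db$families$family]),
               sim$db$families$n_species)
})
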