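params <- cleaning_params()
A3 <- params$adapter3
A5_SEED <- substr(params$adapter5, nchar(params$adapter5) - 7,
                  nchar(params$adapter5))
INSERT21 <- "TGACAGAAGAGAGTGAGCACT"

test_that("classify_read applies the category precedence", {
  expect_equal(classify_read("ACGTACGTACGTACGTACGTACGTACGTACGTACGT")$category,
               "adapter3_null")
  expect_equal(classify_read(paste0(A3, "ACGTACGT"))$category, "insert_null")
  r5 <- classify_read(paste0(A5_SEED, INSERT21, A3))
  expect_equal(r5$category, "adapter5_contaminant")
  expect_equal(classify_read(paste0(substr(INSERT21, 1, 17), A3))$category,
               "smaller_than_min")
  expect_equal(classify_read(paste0(strrep("A", 20), A3))$category, "poly_a")
  cl <- classify_read(paste0(INSERT21, A3))
  expect_equal(cl$category, "clean")
  expect_equal(cl$insert, INSERT21)
  expect_equal(classify_read(paste0(strrep("AC", 20), A3))$category,
               "over_length")
  # 19/20 A with one error still satisfies the 0.9 poly-A fraction
  expect_equal(classify_read(paste0(strrep("A", 12), "G", strrep("A", 7),
                                    A3))$category, "poly_a")
})

test_that("cleaning report partitions high-quality reads with half-up percentages", {
  rep1 <- cleaning_report(16822412,
                          c(adapter3_null = 12978, insert_null = 1934,
                            adapter5_contaminant = 86857,
                            smaller_than_min = 74711, poly_a = 1608),
                          total_reads = 16912862)
  expect_equal(rep1$count[rep1$type == "Clean_reads"], 16644324)
  expect_equal(rep1$percent[rep1$type == "Clean_reads"], 98.94)
  expect_equal(rep1$percent[rep1$type == "High_quality"], 100)
  expect_equal(rep1$percent[rep1$type == "3' adapter_null"], 0.08)
  expect_equal(rep1$percent[rep1$type == "Insert_null"], 0.01)
  expect_equal(rep1$percent[rep1$type == "5' adapter_contaminants"], 0.52)
  expect_equal(rep1$percent[rep1$type == "Smaller_than_18 nt"], 0.44)
  expect_equal(rep1$percent[rep1$type == "Poly A"], 0.01)
  # partition invariant
  cats <- rep1$count[3:7]
  expect_equal(sum(cats) + rep1$count[rep1$type == "Clean_reads"],
               rep1$count[rep1$type == "High_quality"])

  rep0 <- cleaning_report(500, c(adapter3_null = 0, insert_null = 0,
                                 adapter5_contaminant = 0,
                                 smaller_than_min = 0, poly_a = 0))
  expect_equal(rep0$percent[rep0$type == "Clean_reads"], 100)
})

test_that("clean_library recovers planted contaminant truth exactly", {
  sim <- small_sim()
  cl <- clean_library(sim$lib$reads)
  truth <- table(sim$lib$truth$label)
  get <- function(ty) cl$report$count[cl$report$type == ty]
  expect_equal(get("3' adapter_null"), as.numeric(truth[["adapter3_null"]]))
  expect_equal(get("Insert_null"), as.numeric(truth[["insert_null"]]))
  expect_equal(get("5' adapter_contaminants"),
               as.numeric(truth[["adapter5_contaminant"]]))
  expect_equal(get("Smaller_than_18 nt"),
               as.numeric(truth[["smaller_than_min"]]))
  expect_equal(get("Poly A"), as.numeric(truth[["poly_a"]]))
  expect_equal(get("Clean_reads"), as.numeric(truth[["clean"]]))
  expect_equal(get("High_quality"),
               nrow(sim$lib$reads) - as.numeric(truth[["low_quality"]]))
  # every clean tag is a planted insert
  planted <- unique(as_rna(sim$lib$truth$insert[sim$lib$truth$label == "clean"]))
  expect_setequal(cl$tags$sequence, planted)
})

test_that("cleaning is idempotent on clean inserts and monotone in polya_frac", {
  sim <- small_sim()
  cl <- clean_library(sim$lib$reads)
  reads2 <- data.frame(id = cl$tags$id,
                       sequence = paste0(as_dna(cl$tags$sequence),
                                         cleaning_params()$adapter3),
                       quality = NA_character_, count = cl$tags$count)
  cl2 <- clean_library(reads2)
  expect_equal(sort(cl2$tags$sequence), sort(cl$tags$sequence))
  expect_equal(cl2$tags$count[match(cl$tags$sequence, cl2$tags$sequence)],
               cl$tags$count)

  strictest <- clean_library(sim$lib$reads, cleaning_params(polya_frac = 0.5))
  relaxed <- clean_library(sim$lib$reads, cleaning_params(polya_frac = 1))
  n_clean <- function(x) x$report$count[x$report$type == "Clean_reads"]
  expect_true(n_clean(strictest) <= n_clean(cl))
  expect_true(n_clean(cl) <= n_clean(relaxed))
})

test_that("empty input yields a zero report and no tags", {
  cl <- clean_library(data.frame(id = character(0), sequence = character(0),
                                 quality = character(0), count = integer(0)))
  expect_equal(nrow(cl$tags), 0)
  expect_true(all(cl$report$count == 0))
})

test_that("size distribution weights by redundant counts", {
  tags <- small_rna_tags(
    c(rand_rna(21), rand_rna(24), rand_rna(20), rand_rna(22)),
    c(42, 23, 14, 21))
  sd <- size_distribution(tags)
  expect_equal(sd$percent[sd$length == 21], 42)
  expect_equal(sd$length[which.max(sd$percent)], 21)
  expect_equal(sum(sd$percent), 100, tolerance = 0.02)

  one <- size_distribution(small_rna_tags(rand_rna(23), 5))
  expect_equal(one$percent, 100)
  expect_equal(one$length, 23)
})
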