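#' Parameters for raw-read cleaning
#'
#' Defaults follow common small-RNA library chemistry: TruSeq-style
#' adapters, an 18-30 nt insert window, a poly-A rule of >= 90 percent A
#' (tolerant of 1-2 sequencing errors in an A-homopolymer) and
#' seed-based adapter detection allowing one mismatch.
#'
#' @param adapter3 3' adapter sequence (DNA or RNA).
#' @param adapter5 5' adapter sequence.
#' @param min_len,max_len insert length window in nt.
#' @param polya_frac fraction of A at or above which an insert is called
#'   poly-A, in (0, 1].
#' @param adapter_seed seed length in nt used to locate adapters.
#' @param adapter_max_mismatch mismatches tolerated in the seed.
#' @param min_mean_q minimum mean Phred quality for a read to count as
#'   high-quality (reads below are "low quality" and excluded before
#'   classification).
#' @return a list of class `cleaning_params`.
#' @export
cleaning_params <- function(adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                            adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                            min_len = 18L, max_len = 30L,
                            polya_frac = 0.9,
                            adapter_seed = 8L, adapter_max_mismatch = 1L,
                            min_mean_q = 20) {
  stopifnot(min_len <= max_len, polya_frac > 0, polya_frac <= 1,
            adapter_seed >= 4, adapter_max_mismatch >= 0)
  structure(list(adapter3 = as_dna(adapter3), adapter5 = as_dna(adapter5),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 polya_frac = polya_frac, adapter_seed = as.integer(adapter_seed),
                 adapter_max_mismatch = as.integer(adapter_max_mismatch),
                 min_mean_q = min_mean_q),
            class = "cleaning_params")
}

CONTAMINANT_CATEGORIES <- c("adapter3_null", "insert_null",
                            "adapter5_contaminant", "smaller_than_min", "poly_a")

# Vectorised classification core. Returns category + trimmed insert per
# read (DNA space). Precedence is fixed: adapter3_null, insert_null,
# adapter5_contaminant, smaller_than_min, poly_a, over_length, clean;
# the first matching rule wins.
classify_reads_vec <- function(seqs, params) {
  seqs <- as_dna(seqs)
  n <- length(seqs)
  category <- rep("clean", n)
  seed3 <- substr(params$adapter3, 1, params$adapter_seed)
  subj <- Biostrings::DNAStringSet(gsub("[^ACGT]", "N", seqs))
  m3 <- Biostrings::vmatchPattern(seed3, subj,
                                  max.mismatch = params$adapter_max_mismatch)
  first3 <- vapply(Biostrings::startIndex(m3),
                   function(s) if (is.null(s) || !length(s)) NA_integer_ else min(s),
                   integer(1))
  insert <- ifelse(is.na(first3), "", substr(seqs, 1, first3 - 1))
  category[is.na(first3)] <- "adapter3_null"
  open <- category == "clean"
  category[open & first3 == 1] <- "insert_null"
  open <- category == "clean"
  if (any(open)) {
    seed5 <- substr(params$adapter5,
                    nchar(params$adapter5) - params$adapter_seed + 1,
                    nchar(params$adapter5))
    ins_set <- Biostrings::DNAStringSet(gsub("[^ACGT]", "N", insert[open]))
    m5 <- Biostrings::vmatchPattern(seed5, ins_set,
                                    max.mismatch = params$adapter_max_mismatch)
    has5 <- lengths(Biostrings::startIndex(m5)) > 0
    category[which(open)[has5]] <- "adapter5_contaminant"
  }
  open <- category == "clean"
  category[open & nchar(insert) < params$min_len] <- "smaller_than_min"
  open <- category == "clean"
  a_frac <- ifelse(nchar(insert) > 0,
                   nchar(gsub("[^A]", "", insert)) / nchar(insert), 0)
  category[open & a_frac >= params$polya_frac] <- "poly_a"
  open <- category == "clean"
  category[open & nchar(insert) > params$max_len] <- "over_length"
  list(category = category, insert = insert)
}

#' Classify a single read into a cleaning category
#'
#' Applies the contaminant rules in fixed precedence order (first match
#' wins): no 3' adapter, empty insert, 5' adapter within the insert,
#' insert shorter than `min_len`, poly-A insert, over-length insert;
#' anything else is clean. The read is assumed to have passed the
#' quality gate already.
#'
#' @param record a single-row record data.frame or a sequence string.
#' @param params a [cleaning_params()] object.
#' @return list with `category` (one of `adapter3_null`, `insert_null`,
#'   `adapter5_contaminant`, `smaller_than_min`, `poly_a`,
#'   `over_length`, `clean`) and `insert` (trimmed insert, DNA).
#' @export
classify_read <- function(record, params = cleaning_params()) {
  s <- if (is.character(record)) record else record$sequence
  res <- classify_reads_vec(s, params)
  list(category = res$category[1], insert = res$insert[1])
}

#' Build a cleaning summary report from category counts
#'
#' Percentages are computed against the high-quality read count and
#' rounded half-up to 2 decimals; the high-quality row itself reads
#' 100 percent. Clean reads are the high-quality reads not assigned to
#' any of the five contaminant categories.
#'
#' @param high_quality number of reads passing the quality gate.
#' @param counts named numeric vector with elements `adapter3_null`,
#'   `insert_null`, `adapter5_contaminant`, `smaller_than_min`,
#'   `poly_a`.
#' @param total_reads total raw reads (defaults to `high_quality`).
#' @param min_len insert length floor used in the row label.
#' @return a data.frame of class `cleaning_report` with columns `type`,
#'   `count`, `percent`.
#' @examples
#' cleaning_report(16822412,
#'   c(adapter3_null = 12978, insert_null = 1934,
#'     adapter5_contaminant = 86857, smaller_than_min = 74711,
#'     poly_a = 1608), total_reads = 16912862)
#' @export
cleaning_report <- function(high_quality, counts, total_reads = high_quality,
                            min_len = 18L) {
  counts <- counts[CONTAMINANT_CATEGORIES]
  counts[is.na(counts)] <- 0
  names(counts) <- CONTAMINANT_CATEGORIES
  clean <- high_quality - sum(counts)
  stopifnot(clean >= 0, high_quality <= total_reads)
  type <- c("Total_reads", "High_quality", "3' adapter_null", "Insert_null",
            "5' adapter_contaminants", sprintf("Smaller_than_%d nt", min_len),
            "Poly A", "Clean_reads")
  count <- c(total_reads, high_quality, unname(counts), clean)
  percent <- c(NA, 100,
               round_half_up(100 * unname(counts) / high_quality, 2),
               round_half_up(100 * clean / high_quality, 2))
  out <- data.frame(type = type, count = count, percent = percent,
                    stringsAsFactors = FALSE)
  class(out) <- c("cleaning_report", "data.frame")
  out
}

#' Clean a raw small-RNA library
#'
#' Applies the quality gate (mean Phred >= `min_mean_q`; reads without
#' quality strings are assumed high-quality), classifies every
#' high-quality read into the contaminant categories, trims the 3'
#' adapter and collapses the surviving inserts into unique tags.
#' Over-length inserts (> `max_len`) are excluded from the tag set and
#' reported via the `over_length` attribute, outside the five summary
#' categories.
#'
#' @param records a record data.frame from [read_sequence_file()].
#' @param params a [cleaning_params()] object.
#' @return list with `tags` (a `small_rna_tags` table, RNA alphabet),
#'   `report` (a [cleaning_report()]), `categories` (per-read category
#'   vector for the high-quality reads) and `over_length` (count).
#' @export
clean_library <- function(records, params = cleaning_params()) {
  if (nrow(records) == 0) {
    rep0 <- cleaning_report(0, setNames(numeric(5), CONTAMINANT_CATEGORIES),
                            total_reads = 0, min_len = params$min_len)
    return(list(tags = small_rna_tags(character(0), numeric(0)),
                report = rep0, categories = character(0), over_length = 0))
  }
  w <- records$count %||% rep(NA_real_, nrow(records))
  w[is.na(w)] <- 1
  hq <- rep(TRUE, nrow(records))
  if (!is.null(records$quality) && any(!is.na(records$quality))) {
    meanq <- vapply(records$quality, function(q) {
      if (is.na(q)) return(Inf)
      mean(utf8ToInt(q)) - 33
    }, numeric(1), USE.NAMES = FALSE)
    hq <- meanq >= params$min_mean_q
  }
  total <- sum(w)
  high_quality <- sum(w[hq])
  cls <- classify_reads_vec(records$sequence[hq], params)
  whq <- w[hq]
  counts <- vapply(CONTAMINANT_CATEGORIES,
                   function(cat) sum(whq[cls$category == cat]), numeric(1))
  over_length <- sum(whq[cls$category == "over_length"])
  keep <- cls$category == "clean"
  tags <- collapse_tags(data.frame(id = seq_len(sum(keep)),
                                   sequence = cls$insert[keep],
                                   count = whq[keep]))
  report <- cleaning_report(high_quality, counts, total_reads = total,
                            min_len = params$min_len)
  list(tags = tags, report = report, categories = cls$category,
       over_length = over_length)
}

#' Length distribution of a tag pool
#'
#' Percentages are computed on redundant counts (weighted by tag count)
#' and sum to 100 over the observed lengths.
#'
#' @param tags a `small_rna_tags` table.
#' @return data.frame with columns `length`, `count`, `percent`, ordered
#'   by length.
#' @export
size_distribution <- function(tags) {
  if (nrow(tags) == 0) {
    return(data.frame(length = integer(0), count = numeric(0), percent = numeric(0)))
  }
  len <- nchar(tags$sequence)
  agg <- rowsum(tags$count, group = len)
  out <- data.frame(length = as.integer(rownames(agg)),
                    count = as.numeric(agg[, 1]))
  out <- out[order(out$length), , drop = FALSE]
  out$percent <- round_half_up(100 * out$count / sum(out$count), 2)
  rownames(out) <- NULL
  out
}
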