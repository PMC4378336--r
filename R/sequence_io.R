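#' Read a sequence file into a record table
#'
#' Parses FASTA, FASTQ (Sanger qualities) or collapsed FASTA into a
#' data.frame of sequence records. Collapsed FASTA is the small-RNA
#' convention in which the header carries the redundant read count; both
#' common dialects (`>id_xN` and `>id count=N`) are auto-detected.
#'
#' @param path path to the sequence file.
#' @param format one of `"auto"`, `"fasta"`, `"fastq"`, `"collapsed-fasta"`.
#'   `"auto"` picks FASTQ for `.fq`/`.fastq` extensions and FASTA otherwise.
#' @param rna if `TRUE`, sequences are converted to the RNA alphabet
#'   (T becomes U) on read; otherwise they are returned as found
#'   (uppercased).
#' @return a data.frame with columns `id`, `sequence`, `quality`
#'   (`NA` for FASTA) and `count` (`NA` unless collapsed FASTA), rows in
#'   file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1_x5", "ACGUACGUACGUACGUACGUA"), fa)
#' read_sequence_file(fa, format = "collapsed-fasta")
#' @export
read_sequence_file <- function(path, format = c("auto", "fasta", "fastq", "collapsed-fasta"),
                               rna = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  }

  if (format == "fastq") {
    # strict 4-line Sanger FASTQ with per-record validation (the common
    # Biostrings reader does not surface the length invariant)
    lines <- readLines(path)
    if (length(lines) %% 4 != 0) {
      stop("FASTQ parse error in ", path, ": truncated record near line ",
           length(lines), call. = FALSE)
    }
    n <- length(lines) / 4
    heads <- lines[seq(1, by = 4, length.out = n)]
    seqs <- lines[seq(2, by = 4, length.out = n)]
    plus <- lines[seq(3, by = 4, length.out = n)]
    quals <- lines[seq(4, by = 4, length.out = n)]
    bad_head <- !startsWith(heads, "@") | !startsWith(plus, "+")
    if (any(bad_head)) {
      stop(sprintf("FASTQ parse error in %s: malformed record at line %d",
                   path, (which(bad_head)[1] - 1) * 4 + 1), call. = FALSE)
    }
    bad_len <- nchar(quals) != nchar(seqs)
    if (any(bad_len)) {
      stop(sprintf("FASTQ parse error in %s: quality length != sequence length at line %d",
                   path, (which(bad_len)[1] - 1) * 4 + 4), call. = FALSE)
    }
    rec <- data.frame(id = sub("\\s.*$", "", substring(heads, 2)),
                      sequence = toupper(seqs),
                      quality = quals,
                      count = NA_integer_,
                      stringsAsFactors = FALSE)
  } else {
    set <- tryCatch(
      Biostrings::readBStringSet(path, format = "fasta"),
      error = function(e) stop("FASTA parse error in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    rec <- data.frame(id = names(set),
                      sequence = toupper(as.character(set)),
                      quality = NA_character_,
                      count = NA_integer_,
                      stringsAsFactors = FALSE)
    if (format == "collapsed-fasta") {
      parsed <- parse_collapsed_header(rec$id)
      bad <- is.na(parsed$count)
      if (any(bad)) {
        stop(sprintf("collapsed-FASTA parse error in %s: header without count suffix at record %d ('%s')",
                     path, which(bad)[1], rec$id[which(bad)[1]]), call. = FALSE)
      }
      rec$id <- parsed$id
      rec$count <- parsed$count
    }
  }
  if (any(nchar(rec$sequence) == 0)) {
    stop("parse error in ", path, ": empty sequence record", call. = FALSE)
  }
  if (rna) rec$sequence <- as_rna(rec$sequence)
  rownames(rec) <- NULL
  rec
}

# ">id_xN" and ">id count=N" dialects; returns id without the count token.
parse_collapsed_header <- function(ids) {
  count <- rep(NA_real_, length(ids))
  id <- ids
  m1 <- regmatches(ids, regexec("^(.*)_x([0-9]+)$", ids))
  m2 <- regmatches(ids, regexec("^(\\S+)\\s+count=([0-9]+)", ids))
  for (i in seq_along(ids)) {
    if (length(m1[[i]]) == 3) {
      id[i] <- m1[[i]][2]
      count[i] <- as.numeric(m1[[i]][3])
    } else if (length(m2[[i]]) == 3) {
      id[i] <- m2[[i]][2]
      count[i] <- as.numeric(m2[[i]][3])
    }
  }
  list(id = id, count = count)
}

#' Collapse sequence records into unique tags with counts
#'
#' Small-RNA libraries are summarised as unique tags: one entry per
#' distinct sequence with the redundant read count. Records already
#' carrying counts (collapsed FASTA) contribute their counts; plain
#' records count 1 each. The total redundant count is conserved exactly.
#'
#' @param records a record data.frame as returned by
#'   [read_sequence_file()], or a character vector of sequences.
#' @param rna convert sequences to RNA alphabet before collapsing.
#' @return a data.frame of class `small_rna_tags` with columns `id`
#'   (`tag1`, `tag2`, ... in decreasing count order, ties by sequence),
#'   `sequence` and `count`.
#' @export
collapse_tags <- function(records, rna = TRUE) {
  if (is.character(records)) {
    records <- data.frame(id = seq_along(records), sequence = records,
                          count = NA_integer_, stringsAsFactors = FALSE)
  }
  if (nrow(records) == 0) return(small_rna_tags(character(0), numeric(0)))
  seqs <- if (rna) as_rna(records$sequence) else toupper(records$sequence)
  w <- records$count %||% rep(NA_real_, nrow(records))
  w[is.na(w)] <- 1
  agg <- rowsum(as.numeric(w), group = seqs)
  small_rna_tags(rownames(agg), as.numeric(agg[, 1]))
}

#' Construct a tag table
#'
#' @param sequence character vector of unique tag sequences.
#' @param count numeric vector of redundant counts (>= 1).
#' @return a `small_rna_tags` data.frame ordered by decreasing count,
#'   ties broken by sequence.
#' @export
small_rna_tags <- function(sequence, count) {
  stopifnot(length(sequence) == length(count))
  if (anyDuplicated(sequence)) stop("tag sequences must be unique", call. = FALSE)
  if (length(count) && any(count < 1)) stop("tag counts must be >= 1", call. = FALSE)
  ord <- order(-count, sequence)
  out <- data.frame(id = if (length(sequence)) paste0("tag", seq_along(sequence)) else character(0),
                    sequence = sequence[ord],
                    count = as.numeric(count[ord]),
                    stringsAsFactors = FALSE)
  class(out) <- c("small_rna_tags", "data.frame")
  out
}

#' Expand tags back into one sequence per redundant read
#'
#' Inverse of [collapse_tags()] up to ordering: each tag sequence is
#' repeated `count` times.
#'
#' @param tags a `small_rna_tags` table.
#' @return character vector of sequences.
#' @export
expand_tags <- function(tags) {
  rep(tags$sequence, times = tags$count)
}

#' Write tags as collapsed FASTA
#'
#' Headers use the `>id_xN` dialect.
#'
#' @param tags a `small_rna_tags` table.
#' @param path output path.
#' @export
write_collapsed_fasta <- function(tags, path) {
  lines <- character(0)
  if (nrow(tags)) {
    lines <- as.vector(rbind(sprintf(">%s_x%d", tags$id, as.integer(tags$count)),
                             tags$sequence))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a FASTA file from a record table or named character vector
#'
#' @param x record data.frame (columns `id`, `sequence`) or named
#'   character vector.
#' @param path output path.
#' @param width line-wrap width for sequences.
#' @export
write_fasta <- function(x, path, width = 70) {
  if (is.character(x)) x <- data.frame(id = names(x), sequence = unname(x))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(paste0(">", x$id[i]), con)
    s <- x$sequence[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Write a report table as TSV
#'
#' Writes a header row and tab-separated columns; row order is preserved
#' from the input (each report documents its own deterministic order).
#'
#' @param report a data.frame.
#' @param path output path.
#' @export
write_tabular <- function(report, path) {
  ok <- tryCatch({
    write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("could not write ", path, ": ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read a TSV report back
#'
#' @param path TSV path written by [write_tabular()].
#' @return data.frame.
#' @export
read_tabular <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
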