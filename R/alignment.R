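#' Align two short sequences under a combined edit budget
#'
#' End-to-end (global) alignment with unit costs for substitutions and
#' indels, terminal gaps included. The combined budget models the
#' "up to 3 mismatches or gaps" criterion used when assigning small-RNA
#' tags to known mature miRNAs: a hit is reported only when the minimum
#' number of mismatches plus gaps does not exceed `max_dist`. Among
#' minimum-cost alignments, ties are broken toward more matches, then
#' fewer gaps.
#'
#' @param query RNA string (the tag).
#' @param reference RNA string (the database mature).
#' @param max_dist maximum allowed mismatches + gaps (default 3).
#' @return a list with integer fields `matches`, `mismatches`, `gaps`,
#'   or `NULL` when no alignment fits the budget.
#' @examples
#' align_with_budget("UUGACAGAAGAUAGAGAGCAC", "UUGACAGAAGAUAGAGAGCAC")
#' @export
align_with_budget <- function(query, reference, max_dist = 3L) {
  query <- as_rna(query); reference <- as_rna(reference)
  if (!nzchar(query) || !nzchar(reference)) {
    stop("query and reference must be non-empty", call. = FALSE)
  }
  if (max_dist < 0) stop("max_dist must be >= 0", call. = FALSE)
  if (abs(nchar(query) - nchar(reference)) > max_dist) return(NULL)
  res <- .align_budget_cpp(seq_to_codes(query), seq_to_codes(reference),
                           as.integer(max_dist))
  if (res[1] < 0) return(NULL)
  list(matches = res[1], mismatches = res[2], gaps = res[3])
}
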