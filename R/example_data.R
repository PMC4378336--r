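#' Worked-example jute miRNA tables
#'
#' Mature miRNAs reported in a jute (*Corchorus olitorius*) seedling
#' small-RNA survey, bundled as worked-example inputs: the
#' highest-frequency known miRNA of each family with its best plant
#' homolog and alignment statistics (`"known"`), and the novel
#' hairpin-derived candidates with read counts and reported precursor
#' MFE (`"novel"`, values as printed, including one positive-MFE entry
#' that is evidently a sign typo in the source table). Used throughout
#' the documentation and tests as realistic mature sequences.
#'
#' @param set `"known"` or `"novel"`.
#' @return data.frame; for `"known"`: `group`, `family`, `name`,
#'   `length`, `count`, `sequence`, `homolog`, `matches`, `mismatches`,
#'   `gaps`. For `"novel"`: `name`, `reads`, `sequence`, `length`,
#'   `mfe`.
#' @examples
#' head(jute_mirnas("known"))
#' @export
jute_mirnas <- function(set = c("known", "novel")) {
  set <- match.arg(set)
  f <- system.file("extdata", paste0("jute_", set, "_mirnas.tsv"),
                   package = "plantmir")
  read.delim(f, stringsAsFactors = FALSE)
}
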