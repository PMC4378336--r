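#' Stem-loop RT primer backbone
#'
#' The constant hairpin scaffold onto which the miRNA-specific 6-nt 3'
#' anchor is appended. The shipped default is the widely used 44-nt
#' stem-loop scaffold, giving a 50-nt RT primer once the anchor is
#' added; the universal reverse primer is taken from the backbone's 5'
#' region.
#'
#' @param sequence backbone DNA sequence.
#' @param reverse_region 1-based span of the backbone used as the
#'   universal reverse primer.
#' @return list of class `stemloop_backbone`.
#' @export
stemloop_backbone <- function(sequence = "GTCGTATCCAGTGCAGGGTCCGAGGTATTCGCACTGGATACGAC",
                              reverse_region = c(1L, 20L)) {
  sequence <- as_dna(sequence)
  stopifnot(reverse_region[1] >= 1, reverse_region[2] <= nchar(sequence))
  structure(list(sequence = sequence,
                 reverse_region = as.integer(reverse_region)),
            class = "stemloop_backbone")
}

# SantaLucia unified nearest-neighbour parameters (dH kcal/mol, dS cal/mol/K)
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
           GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2, CC = -19.9)

#' Nearest-neighbour primer melting temperature
#'
#' Unified nearest-neighbour thermodynamics with duplex initiation terms
#' and an entropic salt correction; defaults are 250 mM monovalent-equivalent salt (a magnesium-containing PCR buffer)
#' and 250 nM primer. Deterministic in the sequence.
#'
#' @param primer DNA string (A/C/G/T only).
#' @param na_mM monovalent cation concentration, mM.
#' @param primer_nM primer concentration, nM.
#' @return melting temperature in degrees C.
#' @examples
#' melting_temp("GCGCAGTGAAGGGCAATGAA")
#' @export
melting_temp <- function(primer, na_mM = 250, primer_nM = 250) {
  primer <- as_dna(primer)
  if (!nzchar(primer)) stop("primer must be non-empty", call. = FALSE)
  if (grepl("[^ACGT]", primer)) {
    stop("primer contains non-ACGT characters: ", primer, call. = FALSE)
  }
  n <- nchar(primer)
  if (n < 2) stop("primer too short for nearest-neighbour model", call. = FALSE)
  steps <- substring(primer, 1:(n - 1), 2:n)
  dH <- sum(NN_DH[steps])
  dS <- sum(NN_DS[steps])
  ends <- substring(primer, c(1, n), c(1, n))
  for (e in ends) {
    if (e %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  dS <- dS + 0.368 * (n - 1) * log(na_mM / 1000)
  R <- 1.987
  ct <- primer_nM * 1e-9
  dH * 1000 / (dS + R * log(ct / 4)) - 273.15
}

#' Design a stem-loop RT-PCR primer set for one miRNA
#'
#' The stem-loop RT primer is the backbone followed by the exact DNA
#' reverse complement of the miRNA's last 6 nt (the 3' anchor that
#' confers specificity). The forward primer is the DNA transliteration
#' of the miRNA's first 15 bases with a deterministic GC-rich 5'
#' extension (alternating G/C) grown until the nearest-neighbour melting
#' temperature reaches `tm_target`. The universal reverse primer is the
#' backbone's designated 5' region. The expected end-point amplicon is
#' extension + miRNA length + backbone length and is checked against the
#' 60-70 bp assay window.
#'
#' @param mirna mature miRNA sequence (RNA, >= 18 nt); give a named
#'   vector element or set `name`.
#' @param backbone a [stemloop_backbone()].
#' @param tm_target target forward-primer melting temperature, degrees C.
#' @param max_extension maximum GC extension length in nt.
#' @param name miRNA name for the output.
#' @return list of class `primer_set`: `mirna_name`, `stemloop_rt`,
#'   `forward`, `universal_reverse`, `forward_tm`, `expected_amplicon`.
#'   Warns when the amplicon leaves the 60-70 bp window or the Tm target
#'   is unreachable within `max_extension`.
#' @export
design_primer_set <- function(mirna, backbone = stemloop_backbone(),
                              tm_target = 60, max_extension = 12L,
                              name = NULL) {
  if (is.null(name)) name <- names(mirna) %||% "miRNA"
  mirna <- as_rna(unname(mirna))
  assert_rna(mirna, "miRNA")
  L <- nchar(mirna)
  if (L < 18) stop("miRNA must be at least 18 nt", call. = FALSE)
  anchor <- revcomp(substr(mirna, L - 5, L), "dna")
  stemloop_rt <- paste0(backbone$sequence, anchor)
  core <- as_dna(substr(mirna, 1, 15))
  ext <- ""
  forward <- core
  while (melting_temp(forward) < tm_target && nchar(ext) < max_extension) {
    ext <- paste0(ext, if (nchar(ext) %% 2 == 0) "G" else "C")
    forward <- paste0(ext, core)
  }
  tm <- melting_temp(forward)
  if (tm < tm_target) {
    warning(sprintf("%s: forward primer Tm %.1f below target %.1f at max extension",
                    name, tm, tm_target))
  }
  rv <- backbone$reverse_region
  universal_reverse <- substr(backbone$sequence, rv[1], rv[2])
  amplicon <- nchar(ext) + L + nchar(backbone$sequence)
  if (amplicon < 60 || amplicon > 70) {
    warning(sprintf("%s: expected amplicon %d bp outside the 60-70 bp window",
                    name, amplicon))
  }
  structure(list(mirna_name = name, stemloop_rt = stemloop_rt,
                 forward = forward, universal_reverse = universal_reverse,
                 forward_tm = tm, expected_amplicon = as.integer(amplicon)),
            class = "primer_set")
}

#' Design primer sets for a batch of miRNAs
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param ... passed to [design_primer_set()].
#' @return data.frame with one row per miRNA: name, stem-loop RT primer,
#'   forward primer, universal reverse primer, forward Tm and expected
#'   amplicon size.
#' @export
design_primers <- function(mirnas, ...) {
  rows <- lapply(seq_along(mirnas), function(i) {
    ps <- design_primer_set(mirnas[[i]], name = names(mirnas)[i], ...)
    data.frame(mirna_name = ps$mirna_name, stemloop_rt = ps$stemloop_rt,
               forward = ps$forward, universal_reverse = ps$universal_reverse,
               forward_tm = round(ps$forward_tm, 1),
               expected_amplicon = ps$expected_amplicon,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
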