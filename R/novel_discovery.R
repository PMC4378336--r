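#' Thresholds for novel miRNA candidate evaluation
#'
#' @param mfe_max maximum (least negative) acceptable hairpin MFE,
#'   kcal/mol; the precursor must fold at or below it.
#' @param min_pairs minimum number of paired mature positions in the
#'   miRNA/miRNA* duplex region.
#' @param max_bulge maximum bulge / internal-loop size (consecutive
#'   unpaired nt) tolerated within the mature or star span.
#' @return list of class `novel_thresholds`.
#' @export
novel_thresholds <- function(mfe_max = -20, min_pairs = 16L, max_bulge = 4L) {
  structure(list(mfe_max = mfe_max, min_pairs = as.integer(min_pairs),
                 max_bulge = as.integer(max_bulge)),
            class = "novel_thresholds")
}

#' Map a tag to a genome and excise candidate precursor windows
#'
#' Exact-match mapping on both strands. For each locus two windows are
#' excised: one with the tag near the window 5' end and a long 3' flank,
#' and the mirror; windows are clipped at contig ends. Together the two
#' windows cover precursors with the mature on either arm at the 78-349
#' nt precursor scale.
#'
#' @param tag tag sequence (RNA) or single-row tag table.
#' @param genome record data.frame of genome contigs (DNA or RNA).
#' @param flank_up,flank_down proximal / distal flank sizes in nt.
#' @param max_loci tags mapping to more loci than this are skipped as
#'   repeat-like (returns zero rows).
#' @return data.frame with one row per (locus, window): `chrom`,
#'   `start`, `end` (1-based inclusive genomic), `strand`, `window`
#'   (precursor-sense RNA sequence) and `tag_offset` (1-based position
#'   of the tag within the window).
#' @export
map_and_excise <- function(tag, genome, flank_up = 20L, flank_down = 250L,
                           max_loci = 20L) {
  seq_rna <- as_rna(if (is.character(tag)) tag else tag$sequence)
  pat <- as_dna(seq_rna)
  len <- nchar(pat)
  out <- list()
  for (g in seq_len(nrow(genome))) {
    gseq <- as_dna(genome$sequence[g])
    subj <- Biostrings::DNAString(gseq)
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else revcomp(pat, "dna")
      m <- Biostrings::matchPattern(p, subj)
      for (s in Biostrings::start(m)) {
        e <- s + len - 1
        for (geom in c("short5", "short3")) {
          if (xor(strand == "-", geom == "short5")) {
            ws <- max(1L, s - flank_up); we <- min(nchar(gseq), e + flank_down)
          } else {
            ws <- max(1L, s - flank_down); we <- min(nchar(gseq), e + flank_up)
          }
          win <- substr(gseq, ws, we)
          if (strand == "-") win <- revcomp(win, "dna")
          win <- as_rna(win)
          off <- if (strand == "+") s - ws + 1L else we - e + 1L
          out[[length(out) + 1L]] <- data.frame(
            chrom = genome$id[g], start = ws, end = we, strand = strand,
            window = win, tag_offset = off, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), window = character(0),
                      tag_offset = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  if (nrow(out) / 2 > max_loci) {
    message("tag maps to more than ", max_loci, " loci; skipped as repeat-like")
    return(out[0, , drop = FALSE])
  }
  out
}

#' Evaluate a precursor window against the hairpin criteria
#'
#' Folds the window and checks the novel-miRNA selection criteria:
#' (i) the tag is an unannotated genome-matching tag (satisfied by
#' construction upstream, recorded for completeness); (ii) the mature
#' lies entirely within one arm of the hairpin (it must not straddle
#' the terminal loop); (iii) a star partner with 2-nt 3' overhangs on
#' both strands exists within the stem; (iv) the miRNA/miRNA* duplex
#' region has at least `min_pairs` paired mature positions and no bulge
#' or internal loop larger than `max_bulge` within the mature or star
#' span; (v) the fold MFE is at or below `mfe_max` kcal/mol. All failed
#' criteria are reported, not just the first.
#'
#' @param window precursor-sense RNA window containing the tag exactly
#'   once.
#' @param tag the mature tag sequence (RNA).
#' @param model an [energy_model()].
#' @param thresholds a [novel_thresholds()] object.
#' @return list of class `hairpin_candidate`: `precursor`, `structure`
#'   (a `secondary_structure`), `mfe`, `mature_span`, `star_span`
#'   (2-vectors or NULL), `arm` (`"5p"`/`"3p"`), `pairs_in_duplex`,
#'   `max_bulge`, `criteria` (named logical i-v), `accepted`,
#'   `failed` (labels of failed criteria).
#' @export
evaluate_candidate <- function(window, tag, model = energy_model(),
                               thresholds = novel_thresholds()) {
  window <- as_rna(window); tag <- as_rna(tag)
  hits <- gregexpr(tag, window, fixed = TRUE)[[1]]
  if (hits[1] == -1 || length(hits) != 1) {
    stop("tag must occur exactly once in the window", call. = FALSE)
  }
  m1 <- as.integer(hits[1]); m2 <- m1 + nchar(tag) - 1L
  st <- fold_hairpin(window, model)
  partner <- st$partner
  n <- nchar(window)

  crit <- c(i = TRUE, ii = FALSE, iii = FALSE, iv = FALSE, v = FALSE)

  # terminal loop = region enclosed by the innermost pair of the stem
  paired <- which(partner > 0)
  loop <- NULL
  if (length(paired)) {
    opens <- which(partner > seq_len(n))
    inner <- opens[which.max(opens)]
    loop <- c(inner, partner[inner])  # loop spans (inner, partner) exclusive
    crit["ii"] <- (m2 <= loop[1]) || (m1 >= loop[2])
  }
  arm <- if (!is.null(loop) && m2 <= loop[1]) "5p" else "3p"

  # star via Dicer geometry: 2-nt 3' overhangs on both strands
  star <- NULL
  if (partner[m1] > 0 && m2 - 2 >= m1 && partner[m2 - 2] > 0) {
    bounds <- sort(c(partner[m2 - 2], partner[m1] + 2L))
    if (bounds[1] >= 1 && bounds[2] <= n &&
        (bounds[2] < m1 || bounds[1] > m2)) {
      star <- bounds
      crit["iii"] <- TRUE
    }
  }

  mature_paired <- sum(partner[m1:m2] > 0)
  spans <- c(list(m1:m2), if (!is.null(star)) list(star[1]:star[2]))
  bulges <- vapply(spans, function(idx) {
    r <- rle(partner[idx] == 0)
    if (any(r$values)) max(r$lengths[r$values]) else 0L
  }, integer(1))
  max_b <- max(bulges)
  crit["iv"] <- mature_paired >= thresholds$min_pairs && max_b <= thresholds$max_bulge
  crit["v"] <- st$mfe <= thresholds$mfe_max

  structure(list(precursor = window, structure = st, mfe = st$mfe,
                 mature_span = c(m1, m2), star_span = star, arm = arm,
                 pairs_in_duplex = mature_paired, max_bulge = max_b,
                 criteria = crit, accepted = all(crit),
                 failed = names(crit)[!crit]),
            class = "hairpin_candidate")
}

#' Quantify expression of an accepted novel miRNA
#'
#' Sums the counts of tags whose sequence differs from the mature only
#' within the terminal 3 positions at either end: the middle region
#' (mature positions 4 to length-3) must match exactly, and each
#' terminus may shift or vary by at most 3 nt.
#'
#' @param candidate a `hairpin_candidate` (accepted) or the mature RNA
#'   sequence.
#' @param tags a `small_rna_tags` table.
#' @param end_tol terminal tolerance in nt (default 3).
#' @return total redundant count (numeric).
#' @export
quantify_novel <- function(candidate, tags, end_tol = 3L) {
  mature <- if (inherits(candidate, "hairpin_candidate")) {
    substr(candidate$precursor, candidate$mature_span[1], candidate$mature_span[2])
  } else {
    as_rna(candidate)
  }
  L <- nchar(mature)
  if (L < 2 * end_tol + 5) stop("mature too short to define a middle region", call. = FALSE)
  core <- substr(mature, end_tol + 1, L - end_tol)
  total <- 0
  for (i in seq_len(nrow(tags))) {
    s <- tags$sequence[i]
    pos <- gregexpr(core, s, fixed = TRUE)[[1]]
    if (pos[1] == -1) next
    ok <- any(vapply(pos, function(p) {
      flank5 <- p - 1
      flank3 <- nchar(s) - (p + nchar(core) - 1)
      flank5 <= 2 * end_tol && flank3 <= 2 * end_tol
    }, logical(1)))
    if (ok) total <- total + tags$count[i]
  }
  total
}

#' Discover novel miRNAs from unannotated tags
#'
#' Maps each unannotated tag to the genome, excises candidate windows,
#' evaluates every window against the hairpin criteria and retains, per
#' tag, the accepted candidate with the lowest MFE. Accepted candidates
#' are named `<prefix>-miRN<k>-<arm>` in decreasing order of mature tag
#' count.
#'
#' @param tags unannotated tags (`small_rna_tags`).
#' @param genome record data.frame of genome contigs.
#' @param model an [energy_model()].
#' @param thresholds a [novel_thresholds()] object.
#' @param flank_up,flank_down,max_loci see [map_and_excise()].
#' @param prefix name prefix for accepted candidates.
#' @param all_tags tag table used for expression counting (defaults to
#'   `tags`).
#' @return list with `table` (data.frame: `name`, `reads`, `sequence`,
#'   `length`, `mfe`, `arm`, `chrom`, `start`, `end`, `strand`,
#'   `precursor_length`) and `candidates` (named list of
#'   `hairpin_candidate` objects).
#' @export
discover_novel <- function(tags, genome, model = energy_model(),
                           thresholds = novel_thresholds(),
                           flank_up = 20L, flank_down = 250L, max_loci = 20L,
                           prefix = "col", all_tags = tags) {
  found <- list()
  for (i in seq_len(nrow(tags))) {
    tg <- tags$sequence[i]
    wins <- map_and_excise(tg, genome, flank_up, flank_down, max_loci)
    best <- NULL; best_row <- NULL
    for (w in seq_len(nrow(wins))) {
      cand <- tryCatch(
        evaluate_candidate(wins$window[w], tg, model, thresholds),
        error = function(e) NULL)
      if (is.null(cand) || !cand$accepted) next
      if (is.null(best) || cand$mfe < best$mfe) {
        best <- cand
        best_row <- wins[w, ]
      }
    }
    if (!is.null(best)) {
      found[[length(found) + 1L]] <- list(tag_i = i, cand = best, locus = best_row)
    }
  }
  if (!length(found)) {
    return(list(table = data.frame(name = character(0), reads = numeric(0),
                                   sequence = character(0), length = integer(0),
                                   mfe = numeric(0), arm = character(0),
                                   chrom = character(0), start = integer(0),
                                   end = integer(0), strand = character(0),
                                   precursor_length = integer(0),
                                   stringsAsFactors = FALSE),
                candidates = list()))
  }
  counts <- vapply(found, function(f) tags$count[f$tag_i], numeric(1))
  ord <- order(-counts, vapply(found, function(f) tags$sequence[f$tag_i], ""))
  found <- found[ord]
  rows <- lapply(seq_along(found), function(k) {
    f <- found[[k]]
    cand <- f$cand
    name <- sprintf("%s-miRN%d-%s", prefix, k, cand$arm)
    data.frame(name = name,
               reads = quantify_novel(cand, all_tags),
               sequence = tags$sequence[f$tag_i],
               length = nchar(tags$sequence[f$tag_i]),
               mfe = cand$mfe, arm = cand$arm,
               chrom = f$locus$chrom, start = f$locus$start,
               end = f$locus$end, strand = f$locus$strand,
               precursor_length = nchar(cand$precursor),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  cands <- lapply(found, `[[`, "cand")
  names(cands) <- tab$name
  list(table = tab, candidates = cands)
}
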