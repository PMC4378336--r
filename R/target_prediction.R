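#' Thresholds for plant miRNA target prediction
#'
#' The six rules for plant miRNA/target duplexes: (i) at most
#' `max_score` weighted mismatches in total, G:U wobbles counting 0.5;
#' (ii) no more than `max_contig_mm` contiguous mismatches; (iii) no
#' full mismatch within positions `seed_range` from the miRNA 5' end
#' (G:U tolerated there unless `strict_seed`); (iv) perfect match at the
#' cleavage positions (10-11); (v) weighted mismatch score over
#' positions 1-12 at most `seed_score_max`; (vi) duplex energy at least
#' `min_energy_ratio` percent of the perfect-complement energy.
#'
#' Rules (iii) and (v) as stated in common rule sets conflict if (iii)
#' is read literally (zero mismatches in 2-12 would leave (v) nothing to
#' tolerate); the shipped default reads (iii) as banning full mismatches
#' only, with G:U wobbles in 2-12 tolerated subject to the 2.5 cap of
#' (v). Set `strict_seed = TRUE` to also ban wobbles there.
#'
#' @param max_score total weighted mismatch cap (rule i).
#' @param max_contig_mm contiguous full-mismatch cap (rule ii).
#' @param seed_range positions covered by rule iii (1-based from the
#'   miRNA 5' end).
#' @param strict_seed if `TRUE`, G:U wobbles also violate rule iii.
#' @param cleavage_pos positions requiring perfect match (rule iv).
#' @param seed_score_max weighted cap over positions 1-12 (rule v).
#' @param min_energy_ratio minimum duplex/perfect energy ratio in
#'   percent (rule vi).
#' @return list of class `target_thresholds`.
#' @export
target_thresholds <- function(max_score = 4, max_contig_mm = 2L,
                              seed_range = c(2L, 12L), strict_seed = FALSE,
                              cleavage_pos = c(10L, 11L),
                              seed_score_max = 2.5, min_energy_ratio = 74) {
  structure(list(max_score = max_score, max_contig_mm = as.integer(max_contig_mm),
                 seed_range = as.integer(seed_range), strict_seed = strict_seed,
                 cleavage_pos = as.integer(cleavage_pos),
                 seed_score_max = seed_score_max,
                 min_energy_ratio = min_energy_ratio),
            class = "target_thresholds")
}

#' Score an ungapped miRNA/target duplex
#'
#' Computes per-position pair states by antiparallel complementarity
#' (position 1 = miRNA 5' end), the weighted mismatch score (1 per full
#' mismatch, 0.5 per G:U wobble), the duplex hybridisation energy, the
#' perfect-complement energy and their ratio in percent.
#'
#' @param mirna miRNA sequence (RNA, 5'-3').
#' @param site target site (RNA, 5'-3' on the transcript), same length.
#' @param model an [energy_model()].
#' @return list of class `target_duplex` with `pair_states`,
#'   `mismatch_score`, `gu_count`, `mm_count`, `duplex_energy`,
#'   `perfect_energy`, `energy_ratio`.
#' @export
score_duplex <- function(mirna, site, model = energy_model()) {
  mirna <- as_rna(mirna); site <- as_rna(site)
  if (nchar(mirna) != nchar(site)) {
    stop("site length must equal miRNA length (ungapped duplex)", call. = FALSE)
  }
  states <- duplex_pair_states(mirna, site)
  gu <- sum(states == "GU")
  mm <- sum(states == "mismatch")
  de <- duplex_mfe(mirna, site, pairing = states, model = model)
  pe <- perfect_complement_energy(mirna, model)
  structure(list(pair_states = states,
                 mismatch_score = mm + 0.5 * gu,
                 gu_count = gu, mm_count = mm,
                 duplex_energy = de, perfect_energy = pe,
                 energy_ratio = 100 * de / pe),
            class = "target_duplex")
}

#' Apply the six plant target-prediction rules to a scored duplex
#'
#' @param duplex a `target_duplex` from [score_duplex()].
#' @param thresholds a [target_thresholds()] object.
#' @return character vector of violated rule labels (subset of
#'   `c("i","ii","iii","iv","v","vi")`); empty means the duplex passes.
#' @export
apply_rules <- function(duplex, thresholds = target_thresholds()) {
  th <- thresholds
  states <- duplex$pair_states
  L <- length(states)
  bad <- character(0)
  if (duplex$mismatch_score > th$max_score) bad <- c(bad, "i")
  runs <- rle(states == "mismatch")
  if (any(runs$values & runs$lengths > th$max_contig_mm)) bad <- c(bad, "ii")
  seed <- seq(max(1, th$seed_range[1]), min(L, th$seed_range[2]))
  seed_states <- states[seed]
  iii_bad <- any(seed_states == "mismatch") ||
    (th$strict_seed && any(seed_states == "GU"))
  if (iii_bad) bad <- c(bad, "iii")
  cp <- th$cleavage_pos[th$cleavage_pos <= L]
  if (any(states[cp] != "match")) bad <- c(bad, "iv")
  p12 <- states[seq_len(min(12L, L))]
  v_score <- sum(p12 == "mismatch") + 0.5 * sum(p12 == "GU")
  if (v_score > th$seed_score_max) bad <- c(bad, "v")
  if (duplex$energy_ratio < th$min_energy_ratio) bad <- c(bad, "vi")
  bad
}

#' Scan a transcriptome for miRNA target sites
#'
#' Every window of miRNA length on each transcript (mRNA forward
#' orientation) is scored and the six rules applied. Overlapping passing
#' windows for the same miRNA/transcript are collapsed to the best
#' (lowest mismatch score, then lowest duplex energy). Coordinates are
#' 1-based inclusive on the transcript. The transcript position opposite
#' miRNA positions 10-11 (the expected cleavage site) is reported as
#' metadata.
#'
#' @param mirnas named character vector of miRNA sequences (RNA).
#' @param transcripts record data.frame of transcript sequences.
#' @param thresholds a [target_thresholds()] object.
#' @param model an [energy_model()].
#' @return data.frame: `mirna_name`, `transcript_id`, `start`, `end`,
#'   `mismatch_score`, `gu_count`, `duplex_energy`, `perfect_energy`,
#'   `energy_ratio`, `cleavage_site`.
#' @export
scan_transcriptome <- function(mirnas, transcripts,
                               thresholds = target_thresholds(),
                               model = energy_model()) {
  stopifnot(!is.null(names(mirnas)))
  empty <- data.frame(mirna_name = character(0), transcript_id = character(0),
                      start = integer(0), end = integer(0),
                      mismatch_score = numeric(0), gu_count = integer(0),
                      duplex_energy = numeric(0), perfect_energy = numeric(0),
                      energy_ratio = numeric(0), cleavage_site = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(mirnas) || nrow(transcripts) == 0) return(empty)
  out <- list()
  weight_tab <- local({
    # weight[q, t]: 0 match, 0.5 GU, 1 mismatch for miRNA base q facing
    # transcript base t (antiparallel); code 5 = N, always a mismatch
    w <- matrix(1, 5, 5)
    for (q in 1:4) w[q, WC_PARTNER[q]] <- 0
    w[3, 4] <- 0.5; w[4, 3] <- 0.5
    w
  })
  for (mi in seq_along(mirnas)) {
    mir <- as_rna(mirnas[[mi]])
    q <- seq_to_codes(mir)
    q[is.na(q)] <- 5L
    L <- length(q)
    pe <- perfect_complement_energy(mir, model)
    for (ti in seq_len(nrow(transcripts))) {
      tx <- as_rna(transcripts$sequence[ti])
      Tn <- nchar(tx)
      if (Tn < L) next
      tc <- seq_to_codes(tx)
      tc[is.na(tc)] <- 5L
      n_win <- Tn - L + 1L
      # prefilter on rule (i): weighted score per window
      W <- matrix(0, nrow = L, ncol = n_win)
      for (k in seq_len(L)) {
        faces <- tc[seq(L - k + 1, length.out = n_win)]
        W[k, ] <- weight_tab[q[k], faces]
      }
      cand <- which(colSums(W) <= thresholds$max_score)
      if (!length(cand)) next
      rows <- lapply(cand, function(s) {
        site <- substr(tx, s, s + L - 1)
        d <- score_duplex(mir, site, model)
        if (length(apply_rules(d, thresholds))) return(NULL)
        data.frame(mirna_name = names(mirnas)[mi],
                   transcript_id = transcripts$id[ti],
                   start = s, end = s + L - 1L,
                   mismatch_score = d$mismatch_score,
                   gu_count = d$gu_count,
                   duplex_energy = d$duplex_energy,
                   perfect_energy = d$perfect_energy,
                   energy_ratio = d$energy_ratio,
                   cleavage_site = s + L - 10L,
                   stringsAsFactors = FALSE)
      })
      rows <- do.call(rbind, rows)
      if (is.null(rows) || nrow(rows) == 0) next
      # collapse overlapping passes to the best per cluster
      ord <- order(rows$start)
      rows <- rows[ord, , drop = FALSE]
      cluster <- cumsum(c(1, diff(rows$start) >= L))
      keep <- unlist(lapply(split(seq_len(nrow(rows)), cluster), function(idx) {
        r <- rows[idx, , drop = FALSE]
        idx[order(r$mismatch_score, r$duplex_energy, r$start)[1]]
      }))
      out[[length(out) + 1L]] <- rows[sort(keep), , drop = FALSE]
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise predicted targets by annotation category
#'
#' Generic annotation join: counts predicted target transcripts per
#' category given a transcript-to-category mapping (no ontology logic).
#'
#' @param targets result of [scan_transcriptome()].
#' @param annotation data.frame with columns `transcript_id` and
#'   `category` (a transcript may appear under several categories).
#' @return data.frame `category`, `n_targets`, ordered by decreasing
#'   count then category.
#' @export
annotate_targets <- function(targets, annotation) {
  hits <- unique(targets$transcript_id)
  ann <- annotation[annotation$transcript_id %in% hits, , drop = FALSE]
  if (nrow(ann) == 0) {
    return(data.frame(category = character(0), n_targets = integer(0)))
  }
  tab <- table(ann$category)
  out <- data.frame(category = names(tab), n_targets = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_targets, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
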