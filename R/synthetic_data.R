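#' Configuration for the synthetic small-RNA study generator
#'
#' The defaults emulate the statistical structure of a plant seedling
#' small-RNA library: an 18-30 nt tag pool with the length mode at
#' 21 nt (42.19 percent, with 24 nt and 20 nt next most abundant and
#' 20-24 nt jointly 92.69 percent), contaminant rates matching a
#' typical cleaned Illumina run, heavy-tailed (log-normal) tag counts
#' spanning several orders of magnitude, and hairpin precursors embedded
#' in a random background genome. All randomness flows from `seed`.
#'
#' @param seed integer seed; every generator derives its stream from it.
#' @param genome_length background genome length, nt.
#' @param n_hairpins number of conforming planted precursors.
#' @param n_spoilers number of planted precursors violating one hairpin
#'   criterion each (types cycle over ii, iv, v).
#' @param precursor_len_range precursor length interval, nt (within
#'   [60, 400]; the generator samples within it subject to the excision
#'   window geometry).
#' @param mature_len_weights named probability vector over mature
#'   lengths 18-30.
#' @param n_known_db number of known mature miRNA families in the
#'   synthetic database.
#' @param n_species number of plant species codes used in the database
#'   (drives the conservation table).
#' @param contaminant_fractions named per-read probabilities for the
#'   five contaminant categories.
#' @param low_quality_fraction per-read probability of failing the
#'   quality gate.
#' @param read_depth total sequenced reads.
#' @param read_length instrument read length, nt.
#' @param count_meanlog,count_sdlog log-normal parameters of the tag
#'   count law.
#' @param isomir_fraction probability that a planted mature also yields
#'   a terminal isomiR variant (shift <= 2 nt).
#' @param n_ncrna number of ncRNA exclusion records; `n_ncrna_frag`
#'   of their fragments enter the library.
#' @param n_ncrna_frag see above.
#' @param n_transcripts,transcript_length background transcriptome.
#' @param n_planted_targets compliant target sites planted.
#' @param violator_rules rule labels for single-rule-violating planted
#'   sites (one site each).
#' @param adapter3,adapter5 library adapters (shared with
#'   [cleaning_params()]).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              genome_length = 50000L,
                              n_hairpins = 10L,
                              n_spoilers = 3L,
                              precursor_len_range = c(78L, 240L),
                              mature_len_weights = c(
                                `18` = 0.015, `19` = 0.020, `20` = 0.1425,
                                `21` = 0.4219, `22` = 0.080, `23` = 0.053,
                                `24` = 0.2295, `25` = 0.015, `26` = 0.008,
                                `27` = 0.006, `28` = 0.004, `29` = 0.003,
                                `30` = 0.0021),
                              n_known_db = 20L,
                              n_species = 12L,
                              contaminant_fractions = c(
                                adapter3_null = 0.00077,
                                insert_null = 0.00012,
                                adapter5_contaminant = 0.00516,
                                smaller_than_min = 0.00444,
                                poly_a = 0.0001),
                              low_quality_fraction = 0.005,
                              read_depth = 50000L,
                              read_length = 50L,
                              count_meanlog = 4, count_sdlog = 1.5,
                              isomir_fraction = 0.2,
                              n_ncrna = 6L, n_ncrna_frag = 5L,
                              n_transcripts = 10L,
                              transcript_length = 2000L,
                              n_planted_targets = 10L,
                              violator_rules = c("i", "ii", "iii", "iv"),
                              adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                              adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC") {
  stopifnot(sum(contaminant_fractions) + low_quality_fraction <= 1,
            precursor_len_range[1] >= 60, precursor_len_range[2] <= 400,
            abs(sum(mature_len_weights) - 1) < 1e-6)
  structure(as.list(environment()), class = "simulation_config")
}

SPECIES_CODES <- c("ath", "osa", "vvi", "gma", "mdm", "ptc", "mtr", "bdi",
                   "zma", "stu", "csi", "ghr")

rand_seq <- function(len, comp = c(A = 0.3, C = 0.2, G = 0.2, U = 0.3)) {
  paste(sample(names(comp), len, replace = TRUE, prob = comp), collapse = "")
}

sample_mature_len <- function(config, n = 1) {
  as.integer(sample(names(config$mature_len_weights), n, replace = TRUE,
                    prob = config$mature_len_weights))
}

# Library inserts are screened so that classification recovers the
# planted truth exactly: no 3'/5' adapter seed within one mismatch and
# no near-poly-A composition.
insert_ok <- function(s, config, seed_len = 8L) {
  d <- Biostrings::DNAString(as_dna(s))
  seed3 <- substr(as_dna(config$adapter3), 1, seed_len)
  a5 <- as_dna(config$adapter5)
  seed5 <- substr(a5, nchar(a5) - seed_len + 1, nchar(a5))
  if (Biostrings::countPattern(seed3, d, max.mismatch = 1) > 0) return(FALSE)
  if (Biostrings::countPattern(seed5, d, max.mismatch = 1) > 0) return(FALSE)
  a_frac <- nchar(gsub("[^A]", "", s)) / nchar(s)
  a_frac < 0.85
}

screened_seq <- function(len, config, comp = c(A = 0.3, C = 0.2, G = 0.2, U = 0.3)) {
  repeat {
    s <- rand_seq(len, comp)
    if (insert_ok(s, config)) return(s)
  }
}

#' Generate a synthetic known-miRNA database
#'
#' One family per entry group: a random mature carried by a random
#' number of species (near-identical orthologs, at most one
#' substitution apart), named in miRBase style `xxx-miR<num>a`. The
#' species spread drives the conservation classification downstream.
#'
#' @param config a [simulation_config()].
#' @return list with `db` (record data.frame) and `families`
#'   (data.frame: `family`, `base_sequence`, `n_species`).
#' @export
simulate_known_db <- function(config) {
  set.seed(config$seed + 1L)
  species <- SPECIES_CODES[seq_len(config$n_species)]
  entries <- list()
  fam_rows <- list()
  for (f in seq_len(config$n_known_db)) {
    fam <- paste0("miR", 100 + f)
    len <- sample_mature_len(config)
    base <- screened_seq(len, config)
    n_sp <- sample.int(config$n_species, 1)
    carriers <- sample(species, n_sp)
    for (k in seq_along(carriers)) {
      s <- base
      if (k > 1 && runif(1) < 0.5) {
        pos <- sample.int(len, 1)
        substr(s, pos, pos) <- sample(setdiff(RNA_BASES, substr(s, pos, pos)), 1)
      }
      entries[[length(entries) + 1L]] <- data.frame(
        id = paste0(carriers[k], "-", fam, "a"), sequence = s,
        stringsAsFactors = FALSE)
    }
    fam_rows[[f]] <- data.frame(family = fam, base_sequence = base,
                                n_species = n_sp, stringsAsFactors = FALSE)
  }
  list(db = do.call(rbind, entries), families = do.call(rbind, fam_rows))
}

# Build one planted hairpin. Conforming precursors are perfect inverted
# repeats around a loop; spoilers are built to violate one criterion:
#   ii - the mature straddles the terminal loop
#   iv - 6 nt deleted from the star arm opposite the mature (a large
#        bulge in the duplex, mature pairing dropping below min_pairs)
#   v  - A/U-only arms chopped into short stacking runs by 2-nt star
#        insertions: all pairs are retained but the stem is too weak to
#        reach -20 kcal/mol
make_hairpin <- function(type, config) {
  repeat {
    Lm <- sample_mature_len(config)
    comp <- if (type == "spoiler_v") c(A = 0.5, C = 0, G = 0, U = 0.5) else
      c(A = 0.3, C = 0.2, G = 0.2, U = 0.3)
    mature <- tryCatch(screened_seq_comp(Lm, config, comp), error = function(e) NULL)
    if (is.null(mature)) next
    loop_len <- sample(8:40, 1)
    lo <- max(30, ceiling((config$precursor_len_range[1] - loop_len) / 2))
    hi <- min(100, floor((min(config$precursor_len_range[2], 240) - loop_len) / 2))
    if (lo + 1 > hi || lo < Lm + 8) lo <- Lm + 8
    if (lo > hi) next
    arm_len <- sample(lo:hi, 1)
    e <- sample(4:(arm_len - Lm - 4), 1)
    f <- arm_len - Lm - e
    loop <- rand_seq(loop_len)
    arm_comp <- comp

    if (type == "spoiler_ii") {
      arm5 <- paste0(rand_seq(e, arm_comp), substr(mature, 1, 10))
      loop2 <- paste0(substr(mature, 11, Lm), rand_seq(loop_len))
      prec <- paste0(arm5, loop2, revcomp(arm5))
      arm <- "5p"
    } else {
      armq <- paste0(rand_seq(e, arm_comp),
                     if (type == "conforming_3p") revcomp(mature) else mature,
                     rand_seq(f, arm_comp))
      star_arm <- revcomp(armq)
      if (type == "spoiler_iv") {
        # partner region of the mature within the star arm (local coords)
        p_lo <- arm_len - (e + Lm) + 1L
        del_at <- p_lo + floor(Lm / 2) - 3L
        star_arm <- paste0(substr(star_arm, 1, del_at - 1),
                           substr(star_arm, del_at + 6, arm_len))
      } else if (type == "spoiler_v") {
        blocks <- substring(star_arm, seq(1, arm_len, 5),
                            pmin(seq(1, arm_len, 5) + 4, arm_len))
        ins <- vapply(seq_len(length(blocks) - 1),
                      function(i) rand_seq(2, c(A = 0.5, C = 0, G = 0, U = 0.5)),
                      character(1))
        star_arm <- paste0(paste0(blocks[-length(blocks)], ins, collapse = ""),
                           blocks[length(blocks)])
      }
      prec <- paste0(armq, loop, star_arm)
      arm <- if (type == "conforming_3p") "3p" else "5p"
    }
    if (length(gregexpr(mature, prec, fixed = TRUE)[[1]]) != 1 ||
        gregexpr(mature, prec, fixed = TRUE)[[1]][1] == -1) next
    return(list(precursor = prec, mature = mature, arm = arm, type = type))
  }
}

screened_seq_comp <- function(len, config, comp) {
  for (i in 1:200) {
    s <- rand_seq(len, comp)
    if (insert_ok(s, config)) return(s)
  }
  stop("could not draw a screened sequence")
}

#' Generate a synthetic genome with planted hairpin precursors
#'
#' A random background genome (single contig) with `n_hairpins`
#' conforming precursors and `n_spoilers` precursors each violating one
#' hairpin criterion, embedded at well-separated positions on random
#' strands. Re-running with the same config yields a byte-identical
#' genome.
#'
#' @param config a [simulation_config()].
#' @return list with `genome` (record data.frame, contig `chr1`) and
#'   `truth` (data.frame: `hairpin_id`, `type`, `mature`, `arm`,
#'   `precursor`, `start`, `end`, `strand`).
#' @export
simulate_genome_and_hairpins <- function(config) {
  set.seed(config$seed + 2L)
  n_total <- config$n_hairpins + config$n_spoilers
  types <- c(rep(c("conforming_5p", "conforming_3p"),
                 length.out = config$n_hairpins),
             if (config$n_spoilers > 0)
               rep(c("spoiler_ii", "spoiler_iv", "spoiler_v"),
                   length.out = config$n_spoilers))
  hairpins <- lapply(types, make_hairpin, config = config)
  slot <- floor(config$genome_length / n_total)
  if (slot < 300 + 600) stop("genome too short for the requested hairpins", call. = FALSE)
  background <- rand_seq(config$genome_length)
  segments <- character(0)
  truth <- list()
  cursor <- 1L
  for (i in seq_len(n_total)) {
    hp <- hairpins[[i]]
    plen <- nchar(hp$precursor)
    start <- (i - 1L) * slot + sample.int(slot - plen - 600L, 1) + 300L
    strand <- sample(c("+", "-"), 1)
    insert_seq <- if (strand == "+") hp$precursor else revcomp(hp$precursor)
    segments <- c(segments, substr(background, cursor, start - 1L), as_rna(insert_seq))
    cursor <- start + plen
    truth[[i]] <- data.frame(hairpin_id = paste0("hp", i), type = hp$type,
                             mature = hp$mature, arm = hp$arm,
                             precursor = hp$precursor,
                             start = start, end = start + plen - 1L,
                             strand = strand, stringsAsFactors = FALSE)
  }
  segments <- c(segments, substr(background, cursor, config$genome_length))
  genome_seq <- paste(segments, collapse = "")
  list(genome = data.frame(id = "chr1", sequence = genome_seq,
                           stringsAsFactors = FALSE),
       truth = do.call(rbind, truth))
}

# terminal isomiR: shift one end by <= 2 nt, trimming into the mature or
# extending with precursor context, keeping the middle region intact
make_isomir <- function(mature, precursor) {
  pos <- regexpr(mature, precursor, fixed = TRUE)[1]
  L <- nchar(mature)
  repeat {
    d5 <- sample(-2:2, 1)
    d3 <- sample(-2:2, 1)
    if (d5 == 0 && d3 == 0) next
    s <- pos + d5
    e <- pos + L - 1 + d3
    if (s < 1 || e > nchar(precursor) || e - s + 1 < 18) next
    return(substr(precursor, s, e))
  }
}

#' Simulate a raw small-RNA sequencing library
#'
#' Reads are drawn per category by a single multinomial over the
#' configured contaminant, low-quality and clean fractions; clean reads
#' split across the planted sources (hairpin matures, their terminal
#' isomiRs, known-family variants within 3 substitutions of the
#' database, and ncRNA fragments) with log-normal weights. Every read
#' is flanked with the 3' adapter as the cleaning stage expects and
#' carries a constant high quality (low-quality reads a constant low
#' quality). Planted insert sequences are screened against accidental
#' adapter-seed and poly-A matches so the cleaning report recovers the
#' planted truth exactly.
#'
#' @param config a [simulation_config()].
#' @param hairpins truth table from [simulate_genome_and_hairpins()].
#' @param known_db result of [simulate_known_db()] (or a compatible
#'   list with `db` and `families`).
#' @return list with `reads` (record data.frame with qualities),
#'   `truth` (per-read data.frame: `read_id`, `label`, `source`,
#'   `insert`), `exclusion_set` (ncRNA records with `class:name` ids)
#'   and `sources` (per-source data.frame with planted insert, type and
#'   count).
#' @export
simulate_library <- function(config, hairpins, known_db) {
  set.seed(config$seed + 3L)

  # ncRNA exclusion records
  classes <- c("rRNA", "tRNA", "snRNA", "snoRNA", "mRNA", "repeat")
  ncrna <- data.frame(
    id = paste0(rep_len(classes, config$n_ncrna), ":nc", seq_len(config$n_ncrna)),
    sequence = vapply(seq_len(config$n_ncrna),
                      function(i) rand_seq(sample(100:300, 1)), character(1)),
    stringsAsFactors = FALSE)

  sources <- list()
  add_source <- function(insert, type, source_id) {
    sources[[length(sources) + 1L]] <<- data.frame(
      insert = insert, type = type, source_id = source_id,
      weight = rlnorm(1, config$count_meanlog, config$count_sdlog),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(hairpins))) {
    add_source(hairpins$mature[i], "novel", hairpins$hairpin_id[i])
    if (startsWith(hairpins$type[i], "conforming") &&
        runif(1) < config$isomir_fraction) {
      iso <- make_isomir(hairpins$mature[i], hairpins$precursor[i])
      if (insert_ok(iso, config)) {
        add_source(iso, "isomir", hairpins$hairpin_id[i])
      }
    }
  }
  for (f in seq_len(nrow(known_db$families))) {
    base <- known_db$families$base_sequence[f]
    repeat {
      d <- sample(0:3, 1, prob = c(0.4, 0.3, 0.2, 0.1))
      s <- base
      if (d > 0) {
        pos <- sample.int(nchar(s), d)
        for (p in pos) substr(s, p, p) <- sample(setdiff(RNA_BASES, substr(s, p, p)), 1)
      }
      if (insert_ok(s, config)) break
    }
    add_source(s, "known", known_db$families$family[f])
  }
  for (k in seq_len(config$n_ncrna_frag)) {
    repeat {
      r <- sample.int(nrow(ncrna), 1)
      len <- sample(20:24, 1)
      st <- sample.int(nchar(ncrna$sequence[r]) - len + 1, 1)
      frag <- substr(ncrna$sequence[r], st, st + len - 1)
      if (insert_ok(frag, config)) break
    }
    add_source(frag, "ncrna", ncrna$id[r])
  }
  sources <- do.call(rbind, sources)

  # category draw over the whole library
  cats <- names(config$contaminant_fractions)
  probs <- c(config$contaminant_fractions, low_quality = config$low_quality_fraction)
  probs <- c(probs, clean = 1 - sum(probs))
  ncat <- as.vector(rmultinom(1, config$read_depth, probs))
  names(ncat) <- names(probs)
  nsrc <- as.vector(rmultinom(1, ncat[["clean"]], sources$weight / sum(sources$weight)))
  sources$count <- nsrc

  a3 <- as_dna(config$adapter3)
  a5 <- as_dna(config$adapter5)
  seed3 <- substr(a3, 1, 8)
  seed5 <- substr(a5, nchar(a5) - 7, nchar(a5))
  rl <- config$read_length
  mk_read <- function(insert_dna) {
    r <- paste0(insert_dna, a3)
    if (nchar(r) < rl) r <- paste0(r, as_dna(rand_seq(rl - nchar(r))))
    substr(r, 1, rl)
  }
  tailsafe <- function(len) {
    repeat {
      t <- as_dna(rand_seq(len))
      if (Biostrings::countPattern(seed3, Biostrings::DNAString(t),
                                   max.mismatch = 1) == 0) return(t)
    }
  }

  seqs <- character(0); labels <- character(0); src <- character(0)
  ins <- character(0)
  emit <- function(n, seq_fun, label, source_id, insert) {
    if (n <= 0) return()
    new <- vapply(seq_len(n), function(i) seq_fun(), character(1))
    seqs <<- c(seqs, new)
    labels <<- c(labels, rep(label, n))
    src <<- c(src, rep(source_id, n))
    ins <<- c(ins, rep(insert, n))
  }
  for (i in seq_len(nrow(sources))) {
    insert_dna <- as_dna(sources$insert[i])
    emit(sources$count[i], function() mk_read(insert_dna), "clean",
         paste0(sources$type[i], ":", sources$source_id[i]), sources$insert[i])
  }
  emit(ncat[["adapter3_null"]], function() {
    repeat {
      r <- as_dna(rand_seq(rl))
      if (Biostrings::countPattern(seed3, Biostrings::DNAString(r),
                                   max.mismatch = 1) == 0) return(r)
    }
  }, "adapter3_null", "contaminant", NA_character_)
  emit(ncat[["insert_null"]], function() {
    substr(paste0(a3, tailsafe(rl)), 1, rl)
  }, "insert_null", "contaminant", NA_character_)
  emit(ncat[["adapter5_contaminant"]], function() {
    mk_read(paste0(seed5, as_dna(screened_seq(21, config))))
  }, "adapter5_contaminant", "contaminant", NA_character_)
  emit(ncat[["smaller_than_min"]], function() {
    mk_read(as_dna(screened_seq(sample(8:17, 1), config)))
  }, "smaller_than_min", "contaminant", NA_character_)
  emit(ncat[["poly_a"]], function() {
    mk_read(strrep("A", 21))
  }, "poly_a", "contaminant", NA_character_)
  emit(ncat[["low_quality"]], function() {
    mk_read(as_dna(rand_seq(21)))
  }, "low_quality", "low_quality", NA_character_)

  ord <- sample.int(length(seqs))
  qual <- ifelse(labels == "low_quality", strrep("#", nchar(seqs)),
                 strrep("I", nchar(seqs)))
  reads <- data.frame(id = sprintf("r%06d", seq_along(seqs)),
                      sequence = seqs[ord],
                      quality = qual[ord],
                      count = NA_integer_,
                      stringsAsFactors = FALSE)
  truth <- data.frame(read_id = reads$id, label = labels[ord],
                      source = src[ord], insert = ins[ord],
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth, exclusion_set = ncrna, sources = sources)
}

# pick a site base that is a full mismatch to miRNA base q (neither
# Watson-Crick nor wobble partner)
mismatch_base <- function(q) {
  partner <- c(A = "U", C = "G", G = "C", U = "A")[q]
  wobble <- c(G = "U", U = "G")[q]
  sample(setdiff(RNA_BASES, c(partner, wobble, NA)), 1)
}

#' Simulate a transcriptome with planted miRNA target sites
#'
#' Background transcripts receive planted sites: compliant sites
#' (perfect complements or near-perfect duplexes satisfying all six
#' target rules) and, per configured rule, one site violating that rule
#' alone. Coordinates are recorded 1-based inclusive.
#'
#' @param config a [simulation_config()].
#' @param mirnas named character vector of miRNA sequences (RNA).
#' @return list with `transcripts` (record data.frame) and `truth`
#'   (data.frame: `transcript_id`, `mirna_name`, `start`, `end`,
#'   `type` one of `compliant` / `violate_<rule>`, `site`).
#' @export
simulate_transcriptome <- function(config, mirnas) {
  set.seed(config$seed + 4L)
  stopifnot(length(mirnas) > 0)
  tx <- vapply(seq_len(config$n_transcripts),
               function(i) rand_seq(config$transcript_length), character(1))
  ids <- sprintf("TX%04d", seq_len(config$n_transcripts))
  truth <- list()

  plant <- function(mir_name, type) {
    mir <- as_rna(mirnas[[mir_name]])
    L <- nchar(mir)
    site <- revcomp(mir)
    set_pos <- function(site, k, base) {
      j <- L - k + 1
      substr(site, j, j) <- base
      site
    }
    mm_at <- function(site, k) set_pos(site, k, mismatch_base(substr(mir, k, k)))
    if (type == "compliant") {
      style <- sample(c("perfect", "mm15", "gu"), 1)
      cand <- site
      if (style == "mm15" && L >= 16) cand <- mm_at(site, 15)
      if (style == "gu") {
        ks <- which(strsplit(mir, "")[[1]] %in% c("G", "U"))
        ks <- ks[ks >= 4 & ks <= 9]
        if (length(ks)) {
          k <- ks[sample.int(length(ks), 1)]
          wob <- c(G = "U", U = "G")[substr(mir, k, k)]
          cand <- set_pos(site, k, unname(wob))
        }
      }
      # compliance is verified, not assumed: a weak duplex could fall
      # below the energy-ratio floor; fall back to the perfect site
      if (length(apply_rules(score_duplex(mir, cand))) == 0) site <- cand
    } else if (type == "violate_i") {
      for (k in seq(L, by = -2, length.out = 5)) site <- mm_at(site, k)
    } else if (type == "violate_ii") {
      for (k in 16:18) if (k <= L) site <- mm_at(site, k)
    } else if (type == "violate_iii") {
      site <- mm_at(site, 6)
    } else if (type == "violate_iv") {
      site <- mm_at(site, 10)
    }
    site
  }

  used <- lapply(seq_len(config$n_transcripts), function(i) integer(0))
  place <- function(site, ti) {
    L <- nchar(site)
    repeat {
      s <- sample.int(config$transcript_length - L - 100, 1) + 50L
      if (!any(abs(used[[ti]] - s) < L + 10)) {
        used[[ti]] <<- c(used[[ti]], s)
        substr(tx[ti], s, s + L - 1) <<- site
        return(s)
      }
    }
  }

  mir_names <- rep_len(names(mirnas), config$n_planted_targets)
  for (p in seq_len(config$n_planted_targets)) {
    ti <- ((p - 1) %% config$n_transcripts) + 1
    site <- plant(mir_names[p], "compliant")
    s <- place(site, ti)
    truth[[length(truth) + 1L]] <- data.frame(
      transcript_id = ids[ti], mirna_name = mir_names[p],
      start = s, end = s + nchar(site) - 1L, type = "compliant",
      site = site, stringsAsFactors = FALSE)
  }
  v_names <- rep_len(names(mirnas), length(config$violator_rules))
  for (v in seq_along(config$violator_rules)) {
    rule <- config$violator_rules[v]
    ti <- ((v - 1) %% config$n_transcripts) + 1
    site <- plant(v_names[v], paste0("violate_", rule))
    s <- place(site, ti)
    truth[[length(truth) + 1L]] <- data.frame(
      transcript_id = ids[ti], mirna_name = v_names[v],
      start = s, end = s + nchar(site) - 1L,
      type = paste0("violate_", rule), site = site, stringsAsFactors = FALSE)
  }
  list(transcripts = data.frame(id = ids, sequence = tx, stringsAsFactors = FALSE),
       truth = do.call(rbind, truth))
}
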