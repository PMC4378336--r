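#' Parse a miRBase-style mature miRNA name
#'
#' Names follow the `xxx-miRNNNsuffix` convention, e.g. `ath-miR157a`,
#' `gma-miR396b-3p`: a species code, the miR numeral defining the
#' family, and an optional member letter / arm suffix.
#'
#' @param name character vector of database names.
#' @return data.frame with columns `species`, `family` (e.g. `miR156`),
#'   `suffix` (member letter and arm, possibly empty) and `ok`
#'   (parseable flag).
#' @export
parse_mirna_name <- function(name) {
  m <- regexec("^([A-Za-z]{2,5})-(mir|miR|MIR)([0-9]+)(.*)$", name)
  parts <- regmatches(name, m)
  species <- family <- suffix <- rep(NA_character_, length(name))
  ok <- lengths(parts) == 5
  species[ok] <- vapply(parts[ok], `[`, "", 2)
  family[ok] <- paste0("miR", vapply(parts[ok], `[`, "", 4))
  suffix[ok] <- vapply(parts[ok], `[`, "", 5)
  family[!ok] <- NA_character_
  data.frame(name = name, species = species, family = family,
             suffix = suffix, ok = ok, stringsAsFactors = FALSE)
}

#' Remove tags matching a non-miRNA ncRNA exclusion set
#'
#' Tags matching rRNA, tRNA, snRNA, snoRNA, mRNA or repeat-derived
#' sequences are excluded before miRNA assignment. A tag is removed when
#' its sequence occurs as an exact substring of any exclusion record
#' (`mode = "substring"`, the default, matching fragments of longer
#' ncRNAs) or exactly equals one (`mode = "exact"`).
#'
#' @param tags a `small_rna_tags` table.
#' @param exclusion_set record data.frame of ncRNA sequences; record ids
#'   of the form `class:name` (e.g. `rRNA:...`) are used to log removal
#'   counts per class.
#' @param mode `"substring"` or `"exact"`.
#' @return the retained tags, with attribute `removed` (a data.frame of
#'   removed tag counts per ncRNA class).
#' @export
filter_ncrna <- function(tags, exclusion_set, mode = c("substring", "exact")) {
  mode <- match.arg(mode)
  if (nrow(tags) == 0 || nrow(exclusion_set) == 0) {
    attr(tags, "removed") <- data.frame(class = character(0), tags = integer(0),
                                        reads = numeric(0))
    return(tags)
  }
  excl <- as_rna(exclusion_set$sequence)
  cls <- ifelse(grepl(":", exclusion_set$id),
                sub(":.*$", "", exclusion_set$id), "other")
  hit_class <- rep(NA_character_, nrow(tags))
  if (mode == "exact") {
    idx <- match(tags$sequence, excl)
    hit_class[!is.na(idx)] <- cls[idx[!is.na(idx)]]
  } else {
    for (k in seq_along(excl)) {
      open <- is.na(hit_class)
      if (!any(open)) break
      hit <- vapply(tags$sequence[open],
                    function(s) grepl(s, excl[k], fixed = TRUE), logical(1),
                    USE.NAMES = FALSE)
      hit_class[which(open)[hit]] <- cls[k]
    }
  }
  removed <- !is.na(hit_class)
  rm_tab <- if (any(removed)) {
    agg_t <- table(hit_class[removed])
    agg_r <- rowsum(tags$count[removed], group = hit_class[removed])
    data.frame(class = names(agg_t), tags = as.integer(agg_t),
               reads = as.numeric(agg_r[names(agg_t), 1]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(class = character(0), tags = integer(0), reads = numeric(0))
  }
  out <- tags[!removed, , drop = FALSE]
  class(out) <- class(tags)
  attr(out, "removed") <- rm_tab
  out
}

#' Assign tags to known mature miRNAs within an edit budget
#'
#' Each tag is aligned end-to-end against every database mature (see
#' [align_with_budget()]); a hit requires mismatches + gaps <=
#' `max_dist`. The best hit minimises mismatches + gaps; remaining ties
#' are resolved toward the database entry with the highest total count
#' of tags hitting it (database usage), then the lexicographically
#' smallest name. The assigned name replaces the homolog's species code
#' with `prefix`.
#'
#' @param tags a `small_rna_tags` table.
#' @param database record data.frame of mature miRNAs with
#'   miRBase-style ids.
#' @param max_dist combined mismatch + gap budget (default 3).
#' @param prefix species prefix for assigned names (default `"col"`).
#' @return data.frame of hits: `tag_id`, `sequence`, `count`, `length`,
#'   `db_name`, `matches`, `mismatches`, `gaps`, `family`,
#'   `assigned_name`. Tags without a hit are absent (use
#'   [unassigned_tags()]); database entries with unparseable names are
#'   skipped with a warning.
#' @export
assign_known <- function(tags, database, max_dist = 3L, prefix = "col") {
  parsed <- parse_mirna_name(database$id)
  if (any(!parsed$ok)) {
    warning(sum(!parsed$ok), " database entries with unparseable names skipped")
    database <- database[parsed$ok, , drop = FALSE]
    parsed <- parsed[parsed$ok, , drop = FALSE]
  }
  empty <- data.frame(tag_id = character(0), sequence = character(0),
                      count = numeric(0), length = integer(0),
                      db_name = character(0), matches = integer(0),
                      mismatches = integer(0), gaps = integer(0),
                      family = character(0), assigned_name = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(tags) == 0 || nrow(database) == 0) return(empty)
  db_seq <- as_rna(database$sequence)
  db_len <- nchar(db_seq)

  # pass 1: per tag, the set of database entries tied at minimum cost
  cand <- vector("list", nrow(tags))
  for (i in seq_len(nrow(tags))) {
    s <- tags$sequence[i]
    feas <- which(abs(nchar(s) - db_len) <= max_dist)
    best_cost <- max_dist + 1L
    rows <- list()
    for (j in feas) {
      a <- if (s == db_seq[j]) {
        list(matches = nchar(s), mismatches = 0L, gaps = 0L)
      } else {
        align_with_budget(s, db_seq[j], max_dist)
      }
      if (is.null(a)) next
      cost <- a$mismatches + a$gaps
      if (cost < best_cost) {
        best_cost <- cost
        rows <- list()
      }
      if (cost == best_cost) rows[[length(rows) + 1L]] <- c(j = j, unlist(a))
    }
    if (length(rows)) cand[[i]] <- do.call(rbind, rows)
  }

  # database usage: total tag count over every tag whose tie set contains
  # the entry; used only to order ties deterministically
  usage <- numeric(nrow(database))
  for (i in seq_len(nrow(tags))) {
    if (!is.null(cand[[i]])) {
      js <- unique(cand[[i]][, "j"])
      usage[js] <- usage[js] + tags$count[i]
    }
  }

  out <- empty
  for (i in seq_len(nrow(tags))) {
    cc <- cand[[i]]
    if (is.null(cc)) next
    ord <- order(-usage[cc[, "j"]], database$id[cc[, "j"]])
    pick <- cc[ord[1], ]
    j <- pick[["j"]]
    assigned <- paste0(prefix, "-", sub("^[A-Za-z]{2,5}-", "", database$id[j]))
    out <- rbind(out, data.frame(
      tag_id = tags$id[i], sequence = tags$sequence[i],
      count = tags$count[i], length = nchar(tags$sequence[i]),
      db_name = database$id[j],
      matches = as.integer(pick[["matches"]]),
      mismatches = as.integer(pick[["mismatches"]]),
      gaps = as.integer(pick[["gaps"]]),
      family = parsed$family[j], assigned_name = assigned,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Tags not assigned to any known miRNA
#'
#' @param tags a `small_rna_tags` table.
#' @param hits result of [assign_known()].
#' @return the subset of `tags` absent from `hits` (these flow to novel
#'   miRNA discovery).
#' @export
unassigned_tags <- function(tags, hits) {
  out <- tags[!(tags$id %in% hits$tag_id), , drop = FALSE]
  class(out) <- class(tags)
  out
}

#' Group known-miRNA hits into families and quantify expression
#'
#' Families are keyed by the miR numeral of the best database hit
#' (members with identical or nearly identical sequences share that
#' numeral). The representative is the member with the highest tag
#' count; family expression sums the counts of the family's tags that
#' align to the representative sequence within the same edit budget, so
#' each tag contributes to at most one family.
#'
#' @param hits result of [assign_known()].
#' @param tags the tag table the hits were derived from (unused columns
#'   ignored; retained for count lookup).
#' @param max_dist edit budget used for the expression re-count.
#' @param family_alias named character vector folding sister numerals
#'   into one family, following the miRBase annotation convention for
#'   super-families (by default miR157 into miR156 and miR165 into
#'   miR166).
#' @return data.frame with one row per family: `family`, `n_members`,
#'   `members` (comma-separated assigned names), `representative`,
#'   `representative_sequence`, `representative_count`, `expression`;
#'   ordered by decreasing expression.
#' @export
group_and_quantify <- function(hits, tags, max_dist = 3L,
                               family_alias = c(miR157 = "miR156",
                                                miR165 = "miR166")) {
  if (nrow(hits) == 0) {
    return(data.frame(family = character(0), n_members = integer(0),
                      members = character(0), representative = character(0),
                      representative_sequence = character(0),
                      representative_count = numeric(0),
                      expression = numeric(0), stringsAsFactors = FALSE))
  }
  aliased <- hits$family %in% names(family_alias)
  hits$family[aliased] <- unname(family_alias[hits$family[aliased]])
  fams <- split(hits, hits$family)
  rows <- lapply(fams, function(h) {
    rep_i <- order(-h$count, h$assigned_name)[1]
    rep_seq <- h$sequence[rep_i]
    qualifies <- vapply(h$sequence, function(s) {
      !is.null(align_with_budget(s, rep_seq, max_dist))
    }, logical(1), USE.NAMES = FALSE)
    data.frame(family = h$family[1],
               n_members = length(unique(h$assigned_name)),
               members = paste(sort(unique(h$assigned_name)), collapse = ","),
               representative = h$assigned_name[rep_i],
               representative_sequence = rep_seq,
               representative_count = h$count[rep_i],
               expression = sum(h$count[qualifies]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$expression, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a species-by-family presence table from a mature database
#'
#' @param database record data.frame with miRBase-style ids.
#' @return logical matrix, rows = species codes, columns = families.
#' @export
build_presence_table <- function(database) {
  parsed <- parse_mirna_name(database$id)
  parsed <- parsed[parsed$ok, , drop = FALSE]
  if (nrow(parsed) == 0) {
    return(matrix(logical(0), 0, 0))
  }
  table(parsed$species, parsed$family) > 0
}

#' Classify family conservation from cross-species presence
#'
#' A family observed in at least `threshold` plant species is conserved.
#' Nonconserved families are split into "defined" (the family numeral
#' appears in the presence table) and "undefined" (absent from it).
#'
#' @param families data.frame from [group_and_quantify()] (or any frame
#'   with a `family` column).
#' @param presence logical species-by-family matrix, e.g. from
#'   [build_presence_table()].
#' @param threshold minimum number of species for conserved status
#'   (default 9).
#' @return `families` with added columns `species_presence`,
#'   `conserved` (logical) and `conservation` (one of `conserved`,
#'   `nonconserved_defined`, `nonconserved_undefined`).
#' @export
classify_conservation <- function(families, presence, threshold = 9L) {
  known <- colnames(presence) %||% character(0)
  pres <- vapply(families$family, function(f) {
    if (f %in% known) sum(presence[, f]) else 0L
  }, numeric(1), USE.NAMES = FALSE)
  families$species_presence <- as.integer(pres)
  families$conserved <- pres >= threshold
  families$conservation <- ifelse(families$conserved, "conserved",
                                  ifelse(families$family %in% known,
                                         "nonconserved_defined",
                                         "nonconserved_undefined"))
  families
}
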