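PAIR_TYPES <- c("AU", "UA", "CG", "GC", "GU", "UG")

#' Nearest-neighbour RNA energy model
#'
#' A compact thermodynamic model for hairpin and duplex free energies:
#' a 6x6 stacking table over the allowed pairs (Watson-Crick plus G:U
#' wobble, values approximating published nearest-neighbour stacking
#' free energies at 37 degrees C, kcal/mol) and logarithmic
#' (Jacobson-Stockmayer-style) size-dependent penalties for hairpin,
#' bulge and internal loops. The model places typical 80-350 nt plant
#' pre-miRNA hairpins in the -20 to -110 kcal/mol range.
#'
#' @param stack_table path to a TSV with columns `pair1`, `pair2`, `dg`;
#'   defaults to the table shipped with the package.
#' @param hairpin,bulge,internal numeric `c(a, b)`: penalty
#'   `a + b * log(size / s0)` with `s0` = 3 (hairpin), 1 (bulge),
#'   2 (internal), kcal/mol.
#' @param mismatch_penalty kcal/mol added per interior mismatch in a
#'   duplex (>= 0).
#' @param pair_bonus kcal/mol added per base pair; 0 in the
#'   thermodynamic model, set to -1 by [unit_energy_model()].
#' @param min_loop minimum hairpin loop size in nt.
#' @param max_interior maximum total bulge/internal loop size considered
#'   between consecutive pairs, nt.
#' @return an object of class `energy_model`.
#' @export
energy_model <- function(stack_table = NULL,
                         hairpin = c(5.4, 1.08),
                         bulge = c(3.8, 1.08),
                         internal = c(4.0, 1.08),
                         mismatch_penalty = 0.5,
                         pair_bonus = 0,
                         min_loop = 3L,
                         max_interior = 30L) {
  if (is.null(stack_table)) {
    stack_table <- system.file("extdata", "stack_energies.tsv", package = "plantmir")
  }
  tab <- read.delim(stack_table, stringsAsFactors = FALSE)
  stack <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_TYPES, PAIR_TYPES))
  stack[cbind(tab$pair1, tab$pair2)] <- tab$dg
  if (anyNA(stack)) stop("stacking table incomplete: 36 pair steps required", call. = FALSE)
  if (!pair_bonus && any(stack >= 0)) stop("stacking energies must be negative", call. = FALSE)
  structure(list(stack = stack, hairpin = hairpin, bulge = bulge,
                 internal = internal, mismatch_penalty = mismatch_penalty,
                 pair_bonus = pair_bonus, min_loop = as.integer(min_loop),
                 max_interior = as.integer(max_interior)),
            class = "energy_model")
}

#' Unit-score energy model
#'
#' -1 per base pair, no stacking terms and no loop penalties: under this
#' model the optimal single-stem fold maximises the number of pairs,
#' which makes [fold_hairpin()] directly comparable with
#' [nussinov_maxpairs()] and with brute-force enumeration.
#'
#' @inheritParams energy_model
#' @return an `energy_model` whose optimum counts pairs.
#' @export
unit_energy_model <- function(min_loop = 3L, max_interior = 30L) {
  m <- energy_model(min_loop = min_loop, max_interior = max_interior,
                    pair_bonus = -1, mismatch_penalty = 0)
  m$stack[] <- 0
  m$hairpin <- c(0, 0)
  m$bulge <- c(0, 0)
  m$internal <- c(0, 0)
  m
}

# Size-indexed penalty vectors for the C++ DP: element s+1 = loop size s.
loop_penalty_vectors <- function(model, n) {
  size <- 0:n
  hp <- ifelse(size >= model$min_loop,
               model$hairpin[1] + model$hairpin[2] * log(pmax(size, 1) / 3), 1e9)
  bu <- ifelse(size >= 1, model$bulge[1] + model$bulge[2] * log(pmax(size, 1)), 1e9)
  io <- ifelse(size >= 2, model$internal[1] + model$internal[2] * log(pmax(size, 1) / 2), 1e9)
  list(hairpin = pmax(hp, 0), bulge = pmax(bu, 0), internal = pmax(io, 0))
}

#' Fold a candidate precursor into its best single-stem hairpin
#'
#' Dynamic programming over multibranch-free nested structures: a single
#' stem with bulges and internal loops around a terminal hairpin loop of
#' at least `min_loop` unpaired bases. Multibranch structures are
#' excluded because every miRNA precursor candidate is a single hairpin;
#' this keeps the search fully checkable by enumeration. Ties are broken
#' toward fewer pairs, then the lexicographically smallest pair set, so
#' the result is deterministic.
#'
#' @param sequence RNA string (A/C/G/U; N allowed, never pairs).
#' @param model an [energy_model()].
#' @return an object of class `secondary_structure`: list with
#'   `sequence`, `partner` (1-based pairing partner per position, 0 =
#'   unpaired), `pairs` (two-column matrix, i < j), `dotbracket` and
#'   `mfe` (kcal/mol; 0 for a structure with no pairs).
#' @examples
#' fold_hairpin("GGGGAAAACCCC")
#' @export
fold_hairpin <- function(sequence, model = energy_model()) {
  sequence <- as_rna(sequence)
  assert_rna(sequence)
  n <- nchar(sequence)
  if (n > 400) stop("sequence longer than 400 nt: beyond precursor scale", call. = FALSE)
  codes <- seq_to_codes(sequence)
  codes[is.na(codes)] <- 0L
  if (n < model$min_loop + 2) {
    return(new_structure(sequence, integer(n), 0))
  }
  pen <- loop_penalty_vectors(model, n)
  res <- .fold_stem_cpp(codes, model$stack, pen$hairpin, pen$bulge, pen$internal,
                        model$pair_bonus, model$min_loop, model$max_interior)
  new_structure(sequence, res$partner, res$mfe)
}

new_structure <- function(sequence, partner, mfe) {
  i <- which(partner > seq_along(partner))
  pairs <- cbind(i = i, j = partner[i])
  structure(list(sequence = sequence, partner = as.integer(partner),
                 pairs = pairs, dotbracket = partner_to_dotbracket(partner),
                 mfe = mfe),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(x$sequence, "\n", x$dotbracket, "\n",
      sprintf("MFE: %.2f kcal/mol, %d pairs\n", x$mfe, nrow(x$pairs)), sep = "")
  invisible(x)
}

#' Convert a partner vector to dot-bracket notation
#'
#' @param partner integer vector: pairing partner per position (1-based),
#'   0 for unpaired.
#' @return dot-bracket string.
#' @export
partner_to_dotbracket <- function(partner) {
  ch <- rep(".", length(partner))
  ch[partner > seq_along(partner)] <- "("
  ch[partner > 0 & partner < seq_along(partner)] <- ")"
  paste(ch, collapse = "")
}

#' Parse dot-bracket notation back to a partner vector
#'
#' @param dotbracket dot-bracket string (nested, single bracket type).
#' @return integer partner vector (0 = unpaired).
#' @export
dotbracket_to_partner <- function(dotbracket) {
  ch <- strsplit(dotbracket, "", fixed = TRUE)[[1]]
  partner <- integer(length(ch))
  stack <- integer(0)
  for (k in seq_along(ch)) {
    if (ch[k] == "(") stack <- c(stack, k)
    else if (ch[k] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string", call. = FALSE)
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- k
      partner[k] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string", call. = FALSE)
  partner
}

#' Maximum number of nested base pairs (Nussinov recursion)
#'
#' The classical cubic dynamic program over all nested structures
#' (bifurcations included), with Watson-Crick plus G:U pairs and a
#' minimum hairpin loop. Serves as an independent cross-check for
#' [fold_hairpin()] under the unit model.
#'
#' @param sequence RNA string, at most 60 nt (oracle scale).
#' @param min_loop minimum hairpin loop size.
#' @return integer: maximum number of pairs.
#' @export
nussinov_maxpairs <- function(sequence, min_loop = 3L) {
  sequence <- as_rna(sequence)
  assert_rna(sequence)
  n <- nchar(sequence)
  if (n > 60) stop("nussinov_maxpairs is an oracle for sequences <= 60 nt", call. = FALSE)
  if (n < min_loop + 2) return(0L)
  codes <- seq_to_codes(sequence)
  codes[is.na(codes)] <- 0L
  can_pair <- function(a, b) {
    (a > 0 && b > 0) && (WC_PARTNER[a] == b || (a == 3 && b == 4) || (a == 4 && b == 3))
  }
  M <- matrix(0L, n, n)
  for (span in (min_loop + 1):(n - 1)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- max(M[i + 1, j], M[i, j - 1])
      if (can_pair(codes[i], codes[j])) best <- max(best, M[i + 1, j - 1] + 1L)
      if (j - i > 1) {
        for (k in i:(j - 1)) best <- max(best, M[i, k] + M[k + 1, j])
      }
      M[i, j] <- best
    }
  }
  as.integer(M[1, n])
}

# Per-position duplex pair states of an antiparallel ungapped duplex:
# miRNA position k (1 = 5' end) faces site position L - k + 1.
duplex_pair_states <- function(mirna, site) {
  q <- seq_to_codes(mirna)
  s <- rev(seq_to_codes(site))
  if (length(q) != length(s)) stop("miRNA and site must have equal length", call. = FALSE)
  state <- rep("mismatch", length(q))
  ok <- !is.na(q) & !is.na(s)
  state[ok & WC_PARTNER[q] == s] <- "match"
  state[ok & ((q == 3 & s == 4) | (q == 4 & s == 3))] <- "GU"
  state
}

#' Hybridisation energy of an ungapped miRNA/target duplex
#'
#' Energy = sum of stacking terms over consecutive paired positions
#' (match or G:U) plus a penalty per interior mismatch. The perfect
#' reverse complement attains the minimum over all sites of equal
#' length.
#'
#' @param mirna RNA string, 5'-3'.
#' @param site RNA string of the target site, 5'-3' on the transcript,
#'   same length as `mirna`.
#' @param pairing optional per-position state vector
#'   (`"match"`/`"GU"`/`"mismatch"`, position 1 = miRNA 5' end);
#'   computed from complementarity when omitted.
#' @param model an [energy_model()].
#' @return duplex free energy in kcal/mol.
#' @export
duplex_mfe <- function(mirna, site, pairing = NULL, model = energy_model()) {
  mirna <- as_rna(mirna); site <- as_rna(site)
  assert_rna(mirna, "miRNA"); assert_rna(site, "site")
  if (nchar(mirna) != nchar(site)) {
    stop("miRNA and site must have equal length (ungapped duplex)", call. = FALSE)
  }
  states <- pairing %||% duplex_pair_states(mirna, site)
  if (length(states) != nchar(mirna)) {
    stop("pairing must cover the full miRNA length", call. = FALSE)
  }
  q <- seq_to_codes(mirna)
  s <- rev(seq_to_codes(site))
  paired <- states != "mismatch"
  e <- 0
  for (k in seq_len(length(q) - 1)) {
    if (paired[k] && paired[k + 1]) {
      p1 <- PAIR_TYPES[pair_code(q[k], s[k])]
      p2 <- PAIR_TYPES[pair_code(q[k + 1], s[k + 1])]
      e <- e + model$stack[p1, p2]
    }
  }
  interior <- which(!paired)
  if (length(interior)) {
    pr <- which(paired)
    if (length(pr)) {
      interior <- interior[interior > min(pr) & interior < max(pr)]
      e <- e + model$mismatch_penalty * length(interior)
    }
  }
  e
}

pair_code <- function(a, b) {
  out <- integer(length(a))
  out[a == 1 & b == 4] <- 1L
  out[a == 4 & b == 1] <- 2L
  out[a == 2 & b == 3] <- 3L
  out[a == 3 & b == 2] <- 4L
  out[a == 3 & b == 4] <- 5L
  out[a == 4 & b == 3] <- 6L
  out[out == 0] <- NA_integer_
  out
}

#' Duplex energy of a miRNA bound to its perfect complement
#'
#' @inheritParams duplex_mfe
#' @return kcal/mol.
#' @export
perfect_complement_energy <- function(mirna, model = energy_model()) {
  duplex_mfe(mirna, revcomp(mirna), model = model)
}
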