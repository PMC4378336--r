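# Independent oracles used by the unit and acceptance tests. These are
# deliberately simple and coded separately from the package internals.

rand_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# --- alignment -------------------------------------------------------------

# Exhaustive enumeration of all global alignments of two short strings;
# returns the lexicographic optimum of (cost, -matches, gaps).
oracle_align_enum <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- c(cost = Inf, matches = -Inf, gaps = Inf)
  rec <- function(i, j, cost, matches, gaps) {
    if (i > length(av) && j > length(bv)) {
      better <- cost < best[["cost"]] ||
        (cost == best[["cost"]] && matches > best[["matches"]]) ||
        (cost == best[["cost"]] && matches == best[["matches"]] &&
           gaps < best[["gaps"]])
      if (better) best <<- c(cost = cost, matches = matches, gaps = gaps)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      hit <- av[i] == bv[j]
      rec(i + 1, j + 1, cost + !hit, matches + hit, gaps)
    }
    if (i <= length(av)) rec(i + 1, j, cost + 1, matches, gaps + 1)
    if (j <= length(bv)) rec(i, j + 1, cost + 1, matches, gaps + 1)
  }
  rec(1, 1, 0, 0, 0)
  best
}

# --- folding ---------------------------------------------------------------

oracle_pair_ok <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
}

# Energy of an explicit single-stem chain of pairs under a plantmir
# energy model, recomputed from first principles.
oracle_chain_energy <- function(chars, chain, model) {
  if (nrow(chain) == 0) return(0)
  e <- nrow(chain) * model$pair_bonus
  for (r in seq_len(nrow(chain) - 1)) {
    i <- chain[r, 1]; j <- chain[r, 2]
    k <- chain[r + 1, 1]; l <- chain[r + 1, 2]
    s1 <- k - i - 1; s2 <- j - l - 1
    if (s1 == 0 && s2 == 0) {
      p1 <- paste0(chars[i], chars[j]); p2 <- paste0(chars[k], chars[l])
      e <- e + model$stack[p1, p2]
    } else if (s1 == 0 || s2 == 0) {
      e <- e + max(model$bulge[1] + model$bulge[2] * log(s1 + s2), 0)
    } else {
      e <- e + max(model$internal[1] + model$internal[2] * log((s1 + s2) / 2), 0)
    }
  }
  last <- chain[nrow(chain), ]
  loop <- last[2] - last[1] - 1
  e + max(model$hairpin[1] + model$hairpin[2] * log(loop / 3), 0)
}

# Minimum energy over ALL single-stem structures by plain recursion
# (no memoisation): enumerates every chain of nested pairs with a
# terminal loop >= min_loop and interior loops <= max_interior.
oracle_fold_min <- function(seq, model) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  best <- 0
  extend <- function(chain) {
    e <- oracle_chain_energy(chars, chain, model)
    last <- chain[nrow(chain), ]
    if (last[2] - last[1] - 1 >= model$min_loop && e < best) best <<- e
    i <- last[1]; j <- last[2]
    for (k in (i + 1):(j - 1)) {
      if (k + model$min_loop + 1 > j - 1) break
      for (l in (j - 1):(k + model$min_loop + 1)) {
        if ((k - i - 1) + (j - l - 1) > model$max_interior) next
        if (oracle_pair_ok(chars[k], chars[l])) {
          extend(rbind(chain, c(k, l)))
        }
      }
    }
  }
  if (n >= model$min_loop + 2) {
    for (i in 1:(n - model$min_loop - 1)) {
      for (j in n:(i + model$min_loop + 1)) {
        if (oracle_pair_ok(chars[i], chars[j])) extend(rbind(c(i, j)))
      }
    }
  }
  best
}

# Maximum nested pairs (bifurcations allowed) by plain recursion over
# all nested structures; oracle for nussinov_maxpairs at tiny n.
oracle_maxpairs <- function(seq, min_loop = 3) {
  chars <- strsplit(seq, "")[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      if (oracle_pair_ok(chars[i], chars[k])) {
        inner <- rec(i + 1, k - 1)
        right <- if (k < j) rec(k + 1, j) else 0L
        best <- max(best, 1L + inner + right)
      }
    }
    best
  }
  rec(1, length(chars))
}

# --- target rules ----------------------------------------------------------

# Plainly coded re-statement of the six plant target rules, applied to a
# pair-state vector and an energy ratio.
oracle_rules <- function(states, ratio, strict_seed = FALSE) {
  bad <- character(0)
  score <- sum(states == "mismatch") + 0.5 * sum(states == "GU")
  if (score > 4) bad <- c(bad, "i")
  run <- 0; worst <- 0
  for (s in states) {
    if (s == "mismatch") run <- run + 1 else run <- 0
    worst <- max(worst, run)
  }
  if (worst > 2) bad <- c(bad, "ii")
  lo <- 2; hi <- min(12, length(states))
  region <- states[lo:hi]
  if (any(region == "mismatch") || (strict_seed && any(region == "GU"))) {
    bad <- c(bad, "iii")
  }
  for (p in c(10, 11)) {
    if (p <= length(states) && states[p] != "match") {
      bad <- c(bad, "iv")
      break
    }
  }
  first12 <- states[1:min(12, length(states))]
  if (sum(first12 == "mismatch") + 0.5 * sum(first12 == "GU") > 2.5) {
    bad <- c(bad, "v")
  }
  if (ratio < 74) bad <- c(bad, "vi")
  bad
}
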