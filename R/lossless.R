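# Lossless framework: certify that a seed family detects every alignment
# within an error budget, by a minimal-cost dynamic program over the seed
# automaton (optionally intersected with a constraint or cost automaton).

#' Cost scheme for alignments with indels
#'
#' Default costs: match 0, color mismatch 2, a mismatch immediately following
#' another mismatch 1 (so an isolated SNP -- two adjacent color mismatches --
#' totals 3), indel 4, and a mismatch immediately following an indel 0 (it
#' belongs to the indel event).
#'
#' @param match,mismatch,mismatch_after_mismatch,indel,mismatch_after_indel
#'   Non-negative integer costs.
#' @return A `cost_scheme` list.
#' @export
cost_scheme <- function(match = 0, mismatch = 2, mismatch_after_mismatch = 1,
                        indel = 4, mismatch_after_indel = 0) {
  sc <- list(match = match, mismatch = mismatch,
             mismatch_after_mismatch = mismatch_after_mismatch,
             indel = indel, mismatch_after_indel = mismatch_after_indel)
  if (any(unlist(sc) < 0)) stop("costs must be non-negative", call. = FALSE)
  structure(sc, class = "cost_scheme")
}

#' Total cost of an alignment under a cost scheme
#'
#' Direct left-to-right fold of the context rules; independent of the
#' automaton machinery (used as its oracle).  The context starts as
#' after-match (a leading mismatch always costs the full mismatch cost), and
#' after the free post-indel mismatch the context returns to after-match.
#'
#' @param alignment Alignment string over '1'/'0'/'I' or integer codes.
#' @param scheme A `cost_scheme`.
#' @return Numeric total cost.
#' @export
alignment_cost <- function(alignment, scheme = cost_scheme()) {
  syms <- alignment_symbols(alignment)
  ctx <- 1L  # 1 = after match, 2 = after mismatch, 3 = after indel
  total <- 0
  for (s in syms) {
    if (s == 1L) {
      total <- total + scheme$match
      ctx <- 1L
    } else if (s == 2L) {
      total <- total + switch(ctx, scheme$mismatch,
                              scheme$mismatch_after_mismatch,
                              scheme$mismatch_after_indel)
      ctx <- if (ctx == 3L) 1L else 2L
    } else {
      total <- total + scheme$indel
      ctx <- 3L
    }
  }
  total
}

#' Weighted context automaton of a cost scheme
#'
#' Three context states (after-match, after-mismatch, after-indel) with
#' per-transition costs; every state is accepting -- the budget itself is
#' enforced by the minimal-cost dynamic program it is intersected into.
#'
#' @param scheme A `cost_scheme`.
#' @param m Read length (kept as metadata; the automaton is homogeneous).
#' @return A weighted `alignment_dfa` in mode `"mmi"`.
#' @export
build_cost_automaton <- function(scheme = cost_scheme(), m = NULL) {
  # states: 1 after-match (initial), 2 after-mismatch, 3 after-indel
  delta <- rbind(c(1L, 2L, 3L),
                 c(1L, 2L, 3L),
                 c(1L, 1L, 3L))   # post-indel mismatch returns to after-match
  cost <- rbind(c(scheme$match, scheme$mismatch, scheme$indel),
                c(scheme$match, scheme$mismatch_after_mismatch, scheme$indel),
                c(scheme$match, scheme$mismatch_after_indel, scheme$indel))
  new_alignment_dfa(delta, 1L, rep(TRUE, 3), "mmi", cost)
}

#' Constraint automaton for an SNP / reading-error / indel budget
#'
#' Accepts exactly the alignments whose mismatches can be decomposed into at
#' most `snp` disjoint adjacent pairs (SNPs in color space) and at most
#' `err` isolated mismatches, with at most `indel` indel symbols, each indel
#' optionally followed by one free mismatch.  Built by determinizing the
#' natural counting NFA.
#'
#' @param snp,err Maximum number of SNPs and of isolated color mismatches.
#' @param indel Maximum number of indels (0 gives a match/mismatch
#'   automaton).
#' @return An `alignment_dfa` (mode `"mm"` when `indel = 0`, else `"mmi"`).
#' @export
build_error_budget_automaton <- function(snp, err, indel = 0L) {
  stopifnot(snp >= 0, err >= 0, indel >= 0)
  k <- as.integer(snp); h <- as.integer(err); j <- as.integer(indel)
  mode <- if (j > 0L) "mmi" else "mm"
  nsym <- if (j > 0L) 3L else 2L
  # NFA states (a used SNPs, b used errs, c used indels, phase)
  # phase 0 = neutral, 1 = mid-pair (one mismatch of an SNP consumed),
  # phase 2 = just after an indel (one free mismatch available)
  nst <- (k + 1L) * (h + 1L) * (j + 1L) * 3L
  sid <- function(a, b, c, ph) {
    ((a * (h + 1L) + b) * (j + 1L) + c) * 3L + ph + 1L
  }
  trans <- rep(list(rep(list(integer(0)), nsym)), nst)
  finals <- logical(nst)
  for (a in 0:k) for (b in 0:h) for (c in 0:j) for (ph in 0:2) {
    q <- sid(a, b, c, ph)
    finals[q] <- ph != 1L
    tm <- integer(0); tx <- integer(0); ti <- integer(0)
    if (ph != 1L) tm <- sid(a, b, c, 0L)           # match: neutral
    if (ph == 1L) {
      if (a < k) tx <- sid(a + 1L, b, c, 0L)       # completes the SNP pair
    } else {
      if (b < h) tx <- c(tx, sid(a, b + 1L, c, 0L))        # isolated mismatch
      if (a < k) tx <- c(tx, sid(a, b, c, 1L))             # starts an SNP pair
      if (ph == 2L) tx <- c(tx, sid(a, b, c, 0L))          # free post-indel
      if (c < j) ti <- sid(a, b, c + 1L, 2L)
    }
    trans[[q]][[1]] <- tm
    trans[[q]][[2]] <- unique(tx)
    if (nsym == 3L) trans[[q]][[3]] <- ti
  }
  nfa <- list(n = nst, init = sid(0L, 0L, 0L, 0L), finals = finals,
              trans = trans)
  minimize_dfa(determinize_nfa(nfa, nsym, mode))
}

#' Constraint automaton for k SNPs and h reading errors
#'
#' The match/mismatch special case of [build_error_budget_automaton()]:
#' alignments with at most k disjoint adjacent mismatch pairs and at most h
#' isolated mismatches (hence at most 2k + h mismatches with at least the
#' excess beyond h paired adjacently).
#'
#' @param k,h Maximum SNPs and isolated reading errors.
#' @param m Read length (metadata only).
#' @return An `alignment_dfa` in mode `"mm"`.
#' @export
build_snp_error_automaton <- function(k, h, m = NULL) {
  build_error_budget_automaton(k, h, 0L)
}

# ---- budgets ---------------------------------------------------------------

#' Error budgets for lossless certification
#'
#' `mismatch_budget(k)`: at most k color mismatches, unconstrained layout.
#' `event_budget(snp, err, indel)`: at most `snp` SNPs (adjacent mismatch
#' pairs), `err` isolated mismatches and `indel` indels.
#' `cost_budget(threshold, scheme)`: all alignments of total cost at most
#' `threshold` under the scheme.
#'
#' @param k Mismatch count.
#' @return A `seed_budget` object.
#' @export
mismatch_budget <- function(k) {
  structure(list(type = "mismatch", k = as.integer(k)), class = "seed_budget")
}

#' @rdname mismatch_budget
#' @param snp,err,indel Event counts.
#' @export
event_budget <- function(snp, err, indel = 0L) {
  structure(list(type = "events", snp = as.integer(snp),
                 err = as.integer(err), indel = as.integer(indel)),
            class = "seed_budget")
}

#' @rdname mismatch_budget
#' @param threshold Total cost threshold.
#' @param scheme A `cost_scheme`.
#' @export
cost_budget <- function(threshold, scheme = cost_scheme()) {
  structure(list(type = "cost", threshold = threshold, scheme = scheme),
            class = "seed_budget")
}

#' @export
print.seed_budget <- function(x, ...) {
  desc <- switch(x$type,
    mismatch = sprintf("<= %d mismatches", x$k),
    events = sprintf("<= %d SNPs, <= %d errors, <= %d indels",
                     x$snp, x$err, x$indel),
    cost = sprintf("total cost <= %g", x$threshold))
  cat(sprintf("<seed_budget> %s\n", desc))
  invisible(x)
}

# ---- the DP ----------------------------------------------------------------

#' Minimal-cost dynamic program for the lossless property
#'
#' Computes, for every automaton state and every step i in 1..m, the minimal
#' cost (number of mismatches, or weighted cost) needed to reach the state;
#' the family is lossless iff at step m every non-final state has cost
#' exceeding the threshold.  Two rolling rows give O(|Q| * |A|) space; the
#' optional witness (the cheapest missed alignment, lexicographically
#' smallest under match < mismatch < indel) needs an extra backward sweep
#' with O(m |Q|) memory.
#'
#' @param dfa An `alignment_dfa`; non-final states at step m are the
#'   potential misses.  If `dfa$cost` is missing, mismatch-counting costs
#'   are used (mismatch and indel cost 1, match 0).
#' @param m Alignment length.
#' @param threshold Budget: lossless iff the minimum missed cost is greater.
#' @param witness Reconstruct a cheapest missed alignment when not lossless.
#' @return A `lossless_verdict`: list with `lossless`, `min_missed_cost`,
#'   `threshold` and (optionally) `witness`.
#' @export
min_cost_dp <- function(dfa, m, threshold, witness = FALSE) {
  n <- nrow(dfa$delta)
  nsym <- ncol(dfa$delta)
  cost <- dfa$cost
  if (is.null(cost)) {
    cost <- matrix(rep(c(0, 1, 1)[seq_len(nsym)], each = n), n, nsym)
  }
  D <- rep(Inf, n)
  D[dfa$initial] <- 0
  scatter_min <- function(values, idx) {
    o <- order(idx, values)
    keep <- !duplicated(idx[o])
    out <- rep(Inf, n)
    out[idx[o][keep]] <- values[o][keep]
    out
  }
  for (i in seq_len(m)) {
    Dn <- rep(Inf, n)
    for (s in seq_len(nsym)) {
      Dn <- pmin(Dn, scatter_min(D + cost[, s], dfa$delta[, s]))
    }
    D <- Dn
  }
  bad <- !dfa$finals
  min_missed <- if (any(bad)) min(D[bad]) else Inf
  verdict <- structure(
    list(lossless = min_missed > threshold, min_missed_cost = min_missed,
         threshold = threshold, witness = NULL),
    class = "lossless_verdict")
  if (witness && !verdict$lossless) {
    verdict$witness <- .dp_witness(dfa$delta, cost, dfa$initial, !dfa$finals,
                                   m, min_missed)
  }
  verdict
}

# Lexicographically smallest minimal-cost string of length L from the
# initial state to a bad state: backward cost-to-go sweep, then a greedy
# forward walk (match < mismatch < indel at ties).
.dp_witness <- function(delta, cost, initial, bad, L, target) {
  n <- nrow(delta)
  nsym <- ncol(delta)
  B <- matrix(Inf, L + 1L, n)
  B[L + 1L, bad] <- 0
  for (i in L:1) {
    for (s in seq_len(nsym)) {
      B[i, ] <- pmin(B[i, ], cost[, s] + B[i + 1L, delta[, s]])
    }
  }
  q <- initial
  acc <- 0
  out <- integer(L)
  for (i in seq_len(L)) {
    for (s in seq_len(nsym)) {
      q2 <- delta[q, s]
      if (acc + cost[q, s] + B[i + 1L, q2] == target) {
        out[i] <- s
        acc <- acc + cost[q, s]
        q <- q2
        break
      }
    }
  }
  paste(ALIGN_CHARS[out], collapse = "")
}

# Variable-length DP for indel-aware budgets: indel columns consume no read
# position, so in-budget alignments have m read columns plus up to j_max
# indel columns.  Scans completion (read position m, "bad" states) at every
# horizon from m to m + j_max.
.lossless_dp_varlen <- function(delta, cost, initial, bad, m, H, threshold,
                                witness = FALSE) {
  n <- nrow(delta)
  nsym <- ncol(delta)
  D <- rep(Inf, n)
  D[initial] <- 0
  scatter_min <- function(values, idx) {
    o <- order(idx, values)
    keep <- !duplicated(idx[o])
    out <- rep(Inf, n)
    out[idx[o][keep]] <- values[o][keep]
    out
  }
  best <- Inf
  best_step <- NA_integer_
  for (i in seq_len(H)) {
    Dn <- rep(Inf, n)
    for (s in seq_len(nsym)) {
      Dn <- pmin(Dn, scatter_min(D + cost[, s], delta[, s]))
    }
    D <- Dn
    if (i >= m && any(bad)) {
      v <- min(D[bad])
      if (v < best) {
        best <- v
        best_step <- i
      }
    }
  }
  verdict <- structure(
    list(lossless = best > threshold, min_missed_cost = best,
         threshold = threshold, witness = NULL),
    class = "lossless_verdict")
  if (witness && !verdict$lossless) {
    verdict$witness <- .dp_witness(delta, cost, initial, bad, best_step, best)
  }
  verdict
}

#' @export
print.lossless_verdict <- function(x, ...) {
  cat(sprintf("<lossless_verdict> %s  (min missed cost %s, threshold %g)\n",
              if (x$lossless) "LOSSLESS" else "NOT lossless",
              if (is.finite(x$min_missed_cost))
                format(x$min_missed_cost) else "Inf",
              x$threshold))
  if (!is.null(x$witness)) cat(sprintf("  witness: %s\n", x$witness))
  invisible(x)
}

#' Certify the lossless property of a seed family
#'
#' Intersects the family hit automaton with the constraint or cost automaton
#' of the budget and runs the minimal-cost dynamic program: the family is
#' lossless iff no in-budget alignment of length m avoids every allowed seed
#' placement.
#'
#' @param family A `seed_family` (its read length sets m unless `m` given).
#' @param budget A `seed_budget` ([mismatch_budget()], [event_budget()],
#'   [cost_budget()]).
#' @param m Alignment length (default `family$m`).
#' @param witness Reconstruct a cheapest missed alignment when not lossless.
#' @return A `lossless_verdict`.
#' @export
check_lossless <- function(family, budget, m = family$m, witness = FALSE) {
  stopifnot(inherits(family, "seed_family"), inherits(budget, "seed_budget"))
  needs_indel <- budget$type == "cost" ||
    (budget$type == "events" && budget$indel > 0L)
  if (budget$type == "mismatch" ||
      (budget$type == "events" && !needs_indel)) {
    fam_dfa <- family_to_dfa(family, mode = "mm")
    if (budget$type == "mismatch") {
      dp <- fam_dfa
      dp$cost <- matrix(rep(c(0, 1), each = nrow(dp$delta)), ncol = 2)
      return(min_cost_dp(dp, m, budget$k, witness))
    }
    cons <- build_snp_error_automaton(budget$snp, budget$err)
    consNeg <- cons
    consNeg$finals <- !cons$finals
    prod <- dfa_product(fam_dfa, consNeg, "OR")  # final = hit or out-of-budget
    prod$cost <- matrix(rep(c(0, 1), each = nrow(prod$delta)), ncol = 2)
    return(min_cost_dp(prod, m, 2L * budget$snp + budget$err, witness))
  }
  # indel-aware certification: unminimized family automaton keeps the read
  # position of every state; indel columns consume no read position.
  fam_dfa <- family_to_dfa(family, mode = "mmi", minimize = FALSE)
  fpos <- attr(fam_dfa, "pos")
  if (budget$type == "events") {
    cons <- build_error_budget_automaton(budget$snp, budget$err, budget$indel)
    j_max <- budget$indel
    threshold <- 2L * budget$snp + budget$err + 2L * budget$indel
  } else {
    cons <- build_cost_automaton(budget$scheme)
    j_max <- if (budget$scheme$indel > 0)
      floor(budget$threshold / budget$scheme$indel) else m
    threshold <- budget$threshold
  }
  consNeg <- cons
  consNeg$finals <- !cons$finals
  prod <- dfa_product(fam_dfa, consNeg, "OR")
  pa <- attr(prod, "pair_a")
  bad <- !prod$finals & fpos[pa] == m
  cost <- prod$cost
  if (is.null(cost)) {
    cost <- matrix(rep(c(0, 1, 1), each = nrow(prod$delta)), ncol = 3)
  }
  .lossless_dp_varlen(prod$delta, cost, prod$initial, bad, m, m + j_max,
                      threshold, witness)
}

#' Brute-force lossless verification (oracle)
#'
#' Enumerates every in-budget alignment of length m explicitly and tests each
#' with the direct placement scan [family_hits()]; exact but exponential.
#' In-budget membership is decided by independent predicates (a greedy run
#' decomposition for event budgets, the [alignment_cost()] fold for cost
#' budgets), not by the constraint automata.
#'
#' @param family A `seed_family`.
#' @param budget A `seed_budget`.
#' @param m Alignment length.
#' @param guard Maximum number of candidate strings (default 1e6).
#' @return A `lossless_verdict` (witness = the first missed string found in
#'   enumeration order).
#' @export
brute_force_lossless <- function(family, budget, m = family$m, guard = 1e6) {
  strings <- .enumerate_budget_strings(budget, m, guard)
  miss_cost <- Inf
  witness <- NULL
  for (rec in strings) {
    if (!family_hits(family, rec$syms)) {
      if (rec$cost < miss_cost) {
        miss_cost <- rec$cost
        witness <- paste(ALIGN_CHARS[rec$syms], collapse = "")
      }
    }
  }
  threshold <- switch(budget$type,
    mismatch = budget$k,
    events = 2L * budget$snp + budget$err + 2L * budget$indel,
    cost = budget$threshold)
  structure(list(lossless = !is.finite(miss_cost),
                 min_missed_cost = miss_cost, threshold = threshold,
                 witness = witness),
            class = "lossless_verdict")
}

# Enumerate all in-budget strings as lists of list(syms, cost).
.enumerate_budget_strings <- function(budget, m, guard) {
  if (budget$type == "mismatch") {
    max_mm <- budget$k
    n_cand <- sum(choose(m, 0:max_mm))
    if (n_cand > guard) stop("enumeration guard exceeded", call. = FALSE)
    out <- list()
    for (a in 0:max_mm) {
      combos <- if (a == 0) list(integer(0)) else
        asplit(utils::combn(m, a), 2)
      for (pos in combos) {
        syms <- rep(1L, m)
        syms[pos] <- 2L
        out[[length(out) + 1L]] <- list(syms = syms, cost = a)
      }
    }
    return(out)
  }
  if (budget$type == "events") {
    k <- budget$snp; h <- budget$err; j <- budget$indel
    max_mm <- 2L * k + h + j      # up to one free mismatch per indel
    feasible <- function(syms) .event_feasible(syms, k, h, j)
    cost_of <- function(syms) sum(syms != 1L)
    return(.enumerate_error_strings(m, max_mm, j, guard, feasible, cost_of))
  }
  # cost budget
  C <- budget$threshold
  sc <- budget$scheme
  max_ind <- if (sc$indel > 0) floor(C / sc$indel) else m
  unit <- min(sc$mismatch, sc$mismatch_after_mismatch)
  max_mm <- if (unit > 0) floor(C / unit) + max_ind else m
  feasible <- function(syms) alignment_cost(syms, sc) <= C
  cost_of <- function(syms) alignment_cost(syms, sc)
  .enumerate_error_strings(m, min(max_mm, m), max_ind, guard, feasible, cost_of)
}

# All strings with m read (non-indel) columns, <= max_mm mismatches and
# <= max_ind indel columns (alignments with j indels have m + j columns),
# filtered by `feasible`; indel and mismatch positions never coincide.
.enumerate_error_strings <- function(m, max_mm, max_ind, guard,
                                     feasible, cost_of) {
  n_cand <- 0
  for (j in 0:max_ind) {
    for (a in 0:min(max_mm, m)) {
      n_cand <- n_cand + choose(m + j, j) * choose(m, a)
    }
  }
  if (n_cand > guard) stop("enumeration guard exceeded", call. = FALSE)
  out <- list()
  for (j in 0:max_ind) {
    L <- m + j
    icombos <- if (j == 0) list(integer(0)) else asplit(utils::combn(L, j), 2)
    for (ipos in icombos) {
      rest <- setdiff(seq_len(L), ipos)
      for (a in 0:min(max_mm, m)) {
        mcombos <- if (a == 0) list(integer(0)) else
          asplit(utils::combn(length(rest), a), 2)
        for (sel in mcombos) {
          syms <- rep(1L, L)
          syms[ipos] <- 3L
          syms[rest[sel]] <- 2L
          if (feasible(syms)) {
            out[[length(out) + 1L]] <- list(syms = syms, cost = cost_of(syms))
          }
        }
      }
    }
  }
  out
}

# Independent in-budget predicate for event budgets: can the mismatches be
# decomposed into <= k adjacent pairs and <= h singles, after at most one
# free mismatch directly following each indel is absorbed?
.event_feasible <- function(syms, k, h, j) {
  if (sum(syms == 3L) > j) return(FALSE)
  ind_pos <- which(syms == 3L)
  free_candidates <- ind_pos[ind_pos < length(syms)]
  free_candidates <- free_candidates[syms[free_candidates + 1L] == 2L]
  # try every subset of free absorptions (j is tiny)
  subsets <- list(integer(0))
  for (p in free_candidates) {
    subsets <- c(subsets, lapply(subsets, function(s) c(s, p + 1L)))
  }
  for (absorbed in subsets) {
    s2 <- syms
    s2[absorbed] <- 1L                      # absorbed mismatches become free
    runs <- rle(s2 == 2L)
    lens <- runs$lengths[runs$values]
    pairs_avail <- sum(lens %/% 2L)
    used_pairs <- min(k, pairs_avail)
    singles <- sum(lens) - 2L * used_pairs
    if (singles <= h) return(TRUE)
  }
  FALSE
}
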