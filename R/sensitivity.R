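# Lossy framework: probability that a seed family hits an alignment drawn
# from a probabilistic alignment model.

#' Seed-family sensitivity by dynamic programming
#'
#' Computes the probability that an alignment of length m drawn from the
#' model is accepted by the hit automaton: a forward dynamic program over
#' (model state x automaton state) pairs, never enumerating strings.  If the
#' model emits indel symbols, the automaton is indel-extended automatically.
#'
#' @param dfa An `alignment_dfa` with absorbing finals (e.g. from
#'   [family_to_dfa()]), or a `seed_family` (converted internally).
#' @param model A `prob_transducer`.
#' @param m Alignment length (at most the model horizon).
#' @return A `sensitivity_result`: list with `value`, `m`, `n_states`.
#' @export
compute_sensitivity <- function(dfa, model, m) {
  if (inherits(dfa, "seed_family")) {
    emits_indel <- if (is.matrix(model$emit)) any(model$emit[, 3] > 0) else
      any(model$emit[, 3, ] > 0)
    dfa <- family_to_dfa(dfa, mode = if (emits_indel) "mmi" else "mm")
  }
  if (m > model_horizon(model)) {
    stop("m exceeds the model horizon", call. = FALSE)
  }
  emits_indel <- if (is.matrix(model$emit)) any(model$emit[, 3] > 0) else
    any(model$emit[, 3, ] > 0)
  if (emits_indel && dfa$mode == "mm") dfa <- indel_extend(dfa)
  if (!finals_absorbing(dfa)) {
    stop("automaton finals must be absorbing (hits would be double-counted)",
         call. = FALSE)
  }
  nq <- nrow(dfa$delta)
  nsym <- ncol(dfa$delta)
  # P[u, q]: probability of model state u and automaton state q
  P <- matrix(0, model$n, nq)
  P[, dfa$initial] <- model$init
  for (i in seq_len(m)) {
    E <- emission_at(model, i)
    newP <- matrix(0, model$n, nq)
    for (s in seq_len(nsym)) {
      w <- model$prob * E[, s]
      live <- which(w > 0)
      if (!length(live)) next
      Ts <- matrix(0, model$n, model$n)     # per-symbol model-state kernel
      for (e in live) {
        Ts[model$from[e], model$to[e]] <- Ts[model$from[e], model$to[e]] + w[e]
      }
      Q <- crossprod(Ts, P)                 # Q[v, q] = sum_u Ts[u, v] P[u, q]
      agg <- rowsum(t(Q), dfa$delta[, s])   # aggregate automaton targets
      tgt <- as.integer(rownames(agg))
      newP[, tgt] <- newP[, tgt] + t(agg)
    }
    P <- newP
  }
  value <- sum(P[, dfa$finals, drop = FALSE])
  structure(list(value = value, m = as.integer(m), n_states = nq),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> value=%.10g  (m=%d, automaton states=%d)\n",
              x$value, x$m, x$n_states))
  invisible(x)
}

#' Brute-force sensitivity by exhaustive enumeration
#'
#' Enumerates every symbol string of length m, sums the model probabilities
#' of those hit by the family using the direct placement scan (honoring
#' position sets and the no-indel-under-a-window rule).  Test oracle,
#' independent of the automaton machinery.
#'
#' @param family A `seed_family`.
#' @param model A `prob_transducer`.
#' @param m Length; guarded at m <= 16 (binary) / 3^m <= 2e6.
#' @return Probability.
#' @export
brute_force_sensitivity <- function(family, model, m) {
  if (m > 16) stop("m too large for exhaustive enumeration", call. = FALSE)
  emits_indel <- if (is.matrix(model$emit)) any(model$emit[, 3] > 0) else
    any(model$emit[, 3, ] > 0)
  nsym <- if (emits_indel) 3L else 2L
  M <- enumerate_strings(m, nsym)
  probs <- string_probabilities(model, M)
  hits <- family_hits_matrix(family, M)
  sum(probs[hits])
}

# Forward probabilities of many strings at once: M is (N x m) with codes 1..3.
string_probabilities <- function(model, M) {
  N <- nrow(M)
  f <- matrix(model$init, N, model$n, byrow = TRUE)
  for (i in seq_len(ncol(M))) {
    E <- emission_at(model, i)
    newf <- matrix(0, N, model$n)
    for (e in seq_along(model$from)) {
      u <- model$from[e]; v <- model$to[e]
      w <- model$prob[e] * E[e, M[, i]]
      newf[, v] <- newf[, v] + f[, u] * w
    }
    f <- newf
  }
  rowSums(f)
}

# Vectorized direct hit scan over string rows (read-coordinate positions:
# indel columns consume no read position).
family_hits_matrix <- function(family, M) {
  hit <- logical(nrow(M))
  nc <- ncol(M)
  has_ind <- any(M == 3L)
  ind_before <- if (has_ind) {
    cs <- t(apply(M == 3L, 1L, cumsum))
    cbind(0L, cs[, -nc, drop = FALSE])    # indel columns before column c
  } else NULL
  for (mem in family$members) {
    req <- strsplit(mem$seed$pattern, "")[[1]] == "#"
    s <- mem$seed$s
    if (s > nc) next
    for (cc in seq_len(nc - s + 1L)) {
      cols <- cc:(cc + s - 1L)
      win <- M[, cols, drop = FALSE]
      ok <- rowSums(win == 3L) == 0L &
        rowSums(win[, req, drop = FALSE] != 1L) == 0L
      if (has_ind) {
        p <- (cc - 1L) - ind_before[, cc]
        ok <- ok & !is.na(match(p, mem$positions))
      } else if (!((cc - 1L) %in% mem$positions)) {
        next
      }
      hit <- hit | ok
    }
  }
  hit
}

#' Background hit probability (selectivity companion)
#'
#' Probability that the family hits an i.i.d. uniform background alignment
#' (match probability 1/4 per color under the 4-letter color alphabet),
#' computed with the same dynamic program.  Selectivity is one minus this
#' value.
#'
#' @param family A `seed_family` or hit `alignment_dfa`.
#' @param m Alignment length.
#' @param p_match Background per-position match probability (default 0.25).
#' @return Probability of a background hit.
#' @export
background_hit_probability <- function(family, m, p_match = 0.25) {
  compute_sensitivity(family, iid_model(p_match), m)$value
}

#' Evaluate seed families: sensitivity and background-hit probability
#'
#' @param families A `seed_family` or list of them.
#' @param model A `prob_transducer`.
#' @param m Alignment length.
#' @return Tibble with one row per family: members, m, sensitivity,
#'   background hit probability.
#' @export
evaluate_families <- function(families, model, m) {
  if (inherits(families, "seed_family")) families <- list(families)
  rows <- lapply(families, function(fam) {
    tibble::tibble(
      family = paste(vapply(fam$members, function(x) x$seed$pattern,
                            character(1)), collapse = ","),
      m = m,
      sensitivity = compute_sensitivity(fam, model, m)$value,
      background_hit = background_hit_probability(fam, m))
  })
  dplyr::bind_rows(rows)
}
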