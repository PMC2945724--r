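# Probabilistic finite-state transducers over the alignment alphabet.
#
# A transducer has states with an initial distribution and a list of
# transitions (from, to, prob); each transition carries an emission
# distribution over the symbols match/mismatch/indel.  Emissions may be
# horizon-dependent (indexed by step 1..m), which is how the rising
# position-dependent reading-error profile enters the model.

#' Construct a probability transducer
#'
#' @param n_states Number of states.
#' @param init Initial distribution (length `n_states`, sums to 1).
#' @param from,to,prob Parallel vectors defining transitions; outgoing
#'   probabilities from each state must sum to 1.
#' @param emit Emission distributions: a matrix (n_transitions x 3) or, for a
#'   horizon-dependent model, a 3-d array (n_transitions x 3 x m).  Rows sum
#'   to 1.
#' @return A `prob_transducer`.
#' @export
new_prob_transducer <- function(n_states, init, from, to, prob, emit) {
  stopifnot(length(init) == n_states,
            length(from) == length(to), length(to) == length(prob))
  ne <- length(from)
  if (is.matrix(emit)) {
    stopifnot(nrow(emit) == ne, ncol(emit) == 3)
  } else {
    stopifnot(length(dim(emit)) == 3, dim(emit)[1] == ne, dim(emit)[2] == 3)
  }
  dimnames(emit) <- NULL
  x <- structure(list(n = as.integer(n_states), init = as.numeric(init),
                      from = as.integer(from), to = as.integer(to),
                      prob = as.numeric(prob), emit = emit),
                 class = "prob_transducer")
  check_stochastic(x)
  x
}

#' Verify the stochasticity invariants of a transducer
#'
#' Outgoing transition probabilities from every state must sum to 1 and every
#' emission distribution must sum to 1 (both within 1e-12); the initial
#' distribution must sum to 1.
#'
#' @param model A `prob_transducer`.
#' @param tol Tolerance.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
check_stochastic <- function(model, tol = 1e-12) {
  if (abs(sum(model$init) - 1) > tol) {
    stop("initial distribution does not sum to 1", call. = FALSE)
  }
  outs <- tapply(model$prob, model$from, sum)
  present <- sort(unique(model$from))
  if (!setequal(present, seq_len(model$n)) || any(abs(outs - 1) > tol)) {
    stop("outgoing transition probabilities must sum to 1 from every state",
         call. = FALSE)
  }
  if (any(model$prob < -tol) || any(model$prob > 1 + tol)) {
    stop("transition probabilities outside [0,1]", call. = FALSE)
  }
  E <- model$emit
  if (is.matrix(E)) {
    if (any(abs(rowSums(E) - 1) > 1e-9) || any(E < -tol)) {
      stop("emission distributions must sum to 1", call. = FALSE)
    }
  } else {
    sums <- apply(E, c(1, 3), sum)
    if (any(abs(sums - 1) > 1e-9) || any(E < -tol)) {
      stop("emission distributions must sum to 1 at every step", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.prob_transducer <- function(x, ...) {
  hd <- if (is.matrix(x$emit)) "homogeneous" else
    sprintf("horizon-dependent (m=%d)", dim(x$emit)[3])
  cat(sprintf("<prob_transducer> %d states, %d transitions, %s emissions\n",
              x$n, length(x$from), hd))
  invisible(x)
}

emission_at <- function(model, step) {
  if (is.matrix(model$emit)) model$emit else model$emit[, , step]
}

model_horizon <- function(model) {
  if (is.matrix(model$emit)) Inf else dim(model$emit)[3]
}

#' Single-state i.i.d. alignment model
#'
#' @param p_match,p_mismatch,p_indel Symbol probabilities (sum to 1).
#' @return A `prob_transducer` with one state.
#' @export
iid_model <- function(p_match, p_mismatch = 1 - p_match - p_indel,
                      p_indel = 0) {
  new_prob_transducer(1L, 1, 1L, 1L, 1,
                      matrix(c(p_match, p_mismatch, p_indel), 1, 3))
}

#' SNP/indel alignment model
#'
#' Three states -- Match, SNP, Indel -- describing events at the nucleotide
#' level, emitting color-level alignment symbols.  From every state the next
#' state is SNP with probability `p_snp`, Indel with `p_indel`, Match
#' otherwise.  A single SNP appears as two adjacent color mismatches
#' (emission MISMATCH 1 on entering and on leaving the SNP state); runs of
#' consecutive SNPs mix color matches and mismatches (0.25/0.75 on the SNP
#' self-loop).  A color indel is preceded by a color mismatch in 3/4 of the
#' cases (0.75/0.25 mismatch/match on Match->Indel), and every transition out
#' of (or looping on) the Indel state emits an indel symbol.
#'
#' @param p_snp,p_indel Event probabilities, `p_snp + p_indel <= 1`.
#' @return A `prob_transducer` with 3 states (1 = Match, 2 = SNP, 3 = Indel).
#' @export
build_snp_indel_model <- function(p_snp, p_indel) {
  if (p_snp < 0 || p_indel < 0 || p_snp + p_indel > 1) {
    stop("need p_snp, p_indel >= 0 and p_snp + p_indel <= 1", call. = FALSE)
  }
  M <- 1L; SNP <- 2L; IND <- 3L
  p_m <- 1 - p_snp - p_indel
  from <- integer(0); to <- integer(0); pr <- numeric(0)
  em <- NULL
  add <- function(f, t, p, e) {
    from <<- c(from, f); to <<- c(to, t); pr <<- c(pr, p)
    em <<- rbind(em, e)
  }
  MATCH1 <- c(1, 0, 0); MM1 <- c(0, 1, 0); IND1 <- c(0, 0, 1)
  MIX <- c(0.25, 0.75, 0)
  add(M, M, p_m, MATCH1)
  add(M, SNP, p_snp, MM1)         # entering SNP: first color of the pair
  add(M, IND, p_indel, MIX)       # indel preceded by a mismatch in 3/4 cases
  add(SNP, M, p_m, MM1)           # leaving SNP: second color of the pair
  add(SNP, SNP, p_snp, MIX)       # consecutive SNPs: match/mismatch mixture
  add(SNP, IND, p_indel, MM1)     # leaving SNP dominates entering Indel
  add(IND, M, p_m, IND1)          # any transition out of Indel emits an indel
  add(IND, SNP, p_snp, IND1)
  add(IND, IND, p_indel, IND1)
  new_prob_transducer(3L, c(1, 0, 0), from, to, pr, em)
}

#' Period-5 reading-error model
#'
#' States are indexed by an error level l in 0..5 and a phase in 0..4; the
#' phase advances by 1 mod 5 every consumed color.  Phases below the current
#' level are error-prone ("red"): a transition consumed at such a phase emits
#' a mismatch with probability `p_err`, all other transitions emit no
#' mismatch at this stage (the rising baseline is added by
#' [apply_position_profile()]).  With probability `p_s` per step the level
#' increases by one (capped at 5), irreversibly marking one more phase; at
#' level 5 every step is error-prone.
#'
#' @param p_err Periodic reading-error probability.
#' @param p_s Per-step switching probability to the next error level.
#' @param m Read length (metadata; the model itself is homogeneous).
#' @param init_level Starting error level (default 0).
#' @return A `prob_transducer` with 30 states.
#' @export
build_reading_error_model <- function(p_err, p_s, m = NULL, init_level = 0L) {
  stopifnot(p_err >= 0, p_err <= 1, p_s >= 0, p_s <= 1)
  lev <- 0:5; ph <- 0:4
  sid <- function(l, f) l * 5L + f + 1L      # state id for (level, phase)
  n <- 30L
  from <- integer(0); to <- integer(0); pr <- numeric(0)
  em <- NULL
  add <- function(f, t, p, e) {
    if (p > 0) {
      from <<- c(from, f); to <<- c(to, t); pr <<- c(pr, p)
      em <<- rbind(em, e)
    }
  }
  for (l in lev) for (f in ph) {
    red <- f < l                              # marked phase => "red" transition
    e <- if (red) c(1 - p_err, p_err, 0) else c(1, 0, 0)
    f2 <- (f + 1L) %% 5L
    if (l < 5L) {
      add(sid(l, f), sid(l, f2), 1 - p_s, e)
      add(sid(l, f), sid(l + 1L, f2), p_s, e)
    } else {
      add(sid(l, f), sid(l, f2), 1, e)
    }
  }
  # states with no outgoing probability mass cannot occur, but delta must be
  # stochastic from every state; p_s = 1 leaves (1 - p_s) = 0 edges out.
  init <- numeric(n)
  init[sid(min(init_level, 5L), 0L)] <- 1
  model <- new_prob_transducer(n, init, from, to, pr, em)
  attr(model, "m") <- m
  model
}

#' Position profile of baseline reading-error probabilities
#'
#' A non-decreasing per-position mismatch floor, by default linear between
#' the start and end error rates (0.01 and 0.1 in the standard SOLiD
#' parameterization).
#'
#' @param m Read length.
#' @param err_start,err_end Baseline error probabilities at the first and
#'   last color.
#' @return Numeric vector of length m (class `position_profile`).
#' @export
position_profile <- function(m, err_start = 0.01, err_end = 0.1) {
  p <- if (m == 1) err_start else
    err_start + (err_end - err_start) * (seq_len(m) - 1) / (m - 1)
  if (any(diff(p) < 0)) stop("profile must be non-decreasing", call. = FALSE)
  structure(p, class = "position_profile")
}

#' Overlay a position-dependent mismatch floor on a model
#'
#' The product with the linear m+1-state position automaton: at step i the
#' mismatch emission probability of every transition becomes the maximum of
#' its own rate and profile[i] (capped by the available match mass, so indel
#' mass is untouched); the match probability absorbs the difference so each
#' emission distribution still sums to 1.  The result is horizon-dependent.
#'
#' @param model A `prob_transducer` with homogeneous emissions.
#' @param profile Numeric vector of length m (e.g. [position_profile()]).
#' @return A horizon-dependent `prob_transducer`.
#' @export
apply_position_profile <- function(model, profile) {
  if (!is.matrix(model$emit)) {
    stop("model emissions are already horizon-dependent", call. = FALSE)
  }
  m <- length(profile)
  ne <- nrow(model$emit)
  E <- array(0, dim = c(ne, 3, m))
  for (i in seq_len(m)) {
    mism <- model$emit[, 2]
    mat <- model$emit[, 1]
    new_mism <- pmin(pmax(mism, profile[i]), mism + mat)
    E[, 2, i] <- new_mism
    E[, 1, i] <- mat - (new_mism - mism)
    E[, 3, i] <- model$emit[, 3]
  }
  new_prob_transducer(model$n, model$init, model$from, model$to, model$prob, E)
}

#' Product of two alignment models with symbol dominance
#'
#' States are pairs, transition probabilities multiply, and for every symbol
#' pair (a from the first model, b from the second) the probability mass
#' p1*p2 goes to the dominant symbol under indel > mismatch > match, so that
#' errors generated by the two sources superpose.
#'
#' @param a,b `prob_transducer`s (either may be horizon-dependent; horizons
#'   must agree when both are).
#' @return The product `prob_transducer`.
#' @export
product_models <- function(a, b) {
  ha <- model_horizon(a); hb <- model_horizon(b)
  if (is.finite(ha) && is.finite(hb) && ha != hb) {
    stop("model horizons differ", call. = FALSE)
  }
  m <- if (is.finite(ha)) ha else if (is.finite(hb)) hb else NULL
  nea <- length(a$from); neb <- length(b$from)
  ia <- rep(seq_len(nea), each = neb)
  ib <- rep(seq_len(neb), times = nea)
  from <- (a$from[ia] - 1L) * b$n + b$from[ib]
  to <- (a$to[ia] - 1L) * b$n + b$to[ib]
  prob <- a$prob[ia] * b$prob[ib]
  n <- a$n * b$n
  init <- as.numeric(t(outer(a$init, b$init)))  # pair (u,v) -> (u-1)*nb + v
  dominate <- function(Ea, Eb) {
    # Ea, Eb: (n_pairs x 3) emission rows; returns dominated emissions
    mat <- Ea[, 1] * Eb[, 1]
    ind <- Ea[, 3] + Eb[, 3] - Ea[, 3] * Eb[, 3]
    cbind(mat, 1 - mat - ind, ind)
  }
  if (is.null(m)) {
    E <- dominate(a$emit[ia, , drop = FALSE], b$emit[ib, , drop = FALSE])
  } else {
    E <- array(0, dim = c(length(from), 3, m))
    for (i in seq_len(m)) {
      E[, , i] <- dominate(emission_at(a, i)[ia, , drop = FALSE],
                           emission_at(b, i)[ib, , drop = FALSE])
    }
  }
  keep <- prob > 0
  new_prob_transducer(n, init, from[keep], to[keep], prob[keep],
                      if (is.matrix(E)) E[keep, , drop = FALSE] else
                        E[keep, , , drop = FALSE])
}

#' Default full alignment model
#'
#' Product of the SNP/indel model and the period-5 reading-error model with
#' the rising baseline profile overlaid: the standard SOLiD parameterization
#' (SNP 0.0085, indel 0.0015, periodic error 0.02, baseline 0.01 to 0.1).
#'
#' @param m Read length.
#' @param params Parameter list; see [default_model_params()].
#' @return A horizon-dependent `prob_transducer`.
#' @export
build_default_model <- function(m, params = default_model_params()) {
  re <- build_reading_error_model(params$p_err, params$p_s, m)
  re <- apply_position_profile(re, position_profile(m, params$err_start,
                                                    params$err_end))
  product_models(build_snp_indel_model(params$p_snp, params$p_indel), re)
}

#' Default alignment-model parameters
#'
#' SNP probability 0.0085, indel probability 0.0015, periodic reading-error
#' probability 0.02, baseline reading-error probabilities 0.01 (read start)
#' to 0.1 (read end), and level-switching probability 0.05 per step.
#'
#' @return Named list.
#' @export
default_model_params <- function() {
  list(p_snp = 0.0085, p_indel = 0.0015, p_err = 0.02, p_s = 0.05,
       err_start = 0.01, err_end = 0.1)
}

#' Read model parameters from a YAML config
#'
#' Unknown keys are kept; missing keys fall back to
#' [default_model_params()].
#'
#' @param path YAML file path.
#' @return Named list of parameters.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_model_params(), cfg)
}

#' Probability of one alignment string under a model
#'
#' Forward algorithm: the sum over state paths of the product of transition
#' and emission probabilities of the observed symbols.
#'
#' @param model A `prob_transducer`.
#' @param alignment Alignment string over '1'/'0'/'I' or integer codes.
#' @return Probability.
#' @export
alignment_probability <- function(model, alignment) {
  syms <- alignment_symbols(alignment)
  if (length(syms) > model_horizon(model)) {
    stop("alignment longer than the model horizon", call. = FALSE)
  }
  f <- model$init
  for (i in seq_along(syms)) {
    E <- emission_at(model, i)
    w <- model$prob * E[, syms[i]]
    contrib <- f[model$from] * w
    f <- numeric(model$n)
    agg <- rowsum(contrib, model$to)
    f[as.integer(rownames(agg))] <- agg[, 1]
  }
  sum(f)
}

#' Total probability over all alignments of a given length
#'
#' Sums [alignment_probability()] over every symbol string of length m by
#' explicit breadth-first enumeration of all prefixes (vectorized); a
#' consistency check that the model is a proper distribution over
#' length-m alignments.
#'
#' @param model A `prob_transducer`.
#' @param m Length (enumeration is 3^m strings; keep m <= 12).
#' @return Total probability (should be 1).
#' @export
total_probability <- function(model, m) {
  if (3^m > 2e6) stop("enumeration too large", call. = FALSE)
  # rows of P: one per enumerated prefix, columns: state forward mass
  P <- matrix(model$init, 1, model$n, byrow = TRUE)
  for (i in seq_len(m)) {
    E <- emission_at(model, i)
    Ms <- lapply(1:3, function(s) {
      Tm <- matrix(0, model$n, model$n)
      w <- model$prob * E[, s]
      for (e in seq_along(w)) {
        Tm[model$from[e], model$to[e]] <- Tm[model$from[e], model$to[e]] + w[e]
      }
      Tm
    })
    P <- rbind(P %*% Ms[[1]], P %*% Ms[[2]], P %*% Ms[[3]])
  }
  sum(P)
}

#' Write a transducer in an extended transition-table text format
#'
#' One line per transition: `from to prob p_match p_mismatch p_indel`
#' (homogeneous emissions only).
#'
#' @param model A `prob_transducer`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
model_write <- function(model, path) {
  if (!is.matrix(model$emit)) {
    stop("only homogeneous-emission models can be dumped", call. = FALSE)
  }
  lines <- c(sprintf("; prob_transducer states=%d", model$n),
             paste("; init", paste(model$init, collapse = " ")),
             sprintf("%d %d %.12g %.12g %.12g %.12g",
                     model$from, model$to, model$prob,
                     model$emit[, 1], model$emit[, 2], model$emit[, 3]))
  writeLines(lines, path)
  invisible(path)
}
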