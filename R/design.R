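# Seed search: sample gap layouts and position sets, score candidates by
# sensitivity (lossy mode) or certify losslessness and rank by selectivity
# (lossless mode), then hill-climb the best candidates.

#' Specify a seed-design problem
#'
#' @param mode `"lossy"` (maximize sensitivity) or `"lossless"` (keep only
#'   certified families, rank by selectivity).
#' @param w Seed weight.
#' @param max_span Maximum seed span (>= w).
#' @param n_positions Allowed positions per member.
#' @param family_size Number of member seeds.
#' @param m Read length.
#' @param model A `prob_transducer` (lossy mode).
#' @param budget A `seed_budget` (lossless mode).
#' @param n_candidates Number of sampled candidates.
#' @param top_k Candidates kept for local optimization.
#' @param opt_steps Hill-climbing step budget per candidate.
#' @param rng_seed Integer seed; the whole search is deterministic given it.
#' @return A `design_problem`.
#' @export
design_problem <- function(mode = c("lossy", "lossless"), w, max_span,
                           n_positions, family_size = 1L, m,
                           model = NULL, budget = NULL,
                           n_candidates = 200L, top_k = 10L, opt_steps = 50L,
                           rng_seed = 0L) {
  mode <- match.arg(mode)
  stopifnot(w >= 1, max_span >= w, n_positions >= 1, family_size >= 1, m >= w)
  if (mode == "lossy" && is.null(model)) {
    stop("lossy mode needs a model", call. = FALSE)
  }
  if (mode == "lossless" && is.null(budget)) {
    stop("lossless mode needs a budget", call. = FALSE)
  }
  structure(list(mode = mode, w = as.integer(w),
                 max_span = as.integer(max_span),
                 n_positions = as.integer(n_positions),
                 family_size = as.integer(family_size), m = as.integer(m),
                 model = model, budget = budget,
                 n_candidates = as.integer(n_candidates),
                 top_k = as.integer(top_k), opt_steps = as.integer(opt_steps),
                 rng_seed = as.integer(rng_seed)),
            class = "design_problem")
}

# Uniformly sample one seed pattern of weight w and span <= max_span:
# choose the span, then which interior slots are gaps.
.sample_pattern <- function(w, max_span) {
  spans <- w:max_span
  feasible <- spans[spans - w <= pmax(spans - 2L, 0L)]
  s <- if (length(feasible) == 1L) feasible else sample(feasible, 1L)
  g <- s - w
  chars <- rep("#", s)
  if (g > 0L) {
    gaps <- sample(seq.int(2L, s - 1L), g)
    chars[gaps] <- "-"
  }
  parse_seed(paste(chars, collapse = ""))
}

#' Sample a candidate seed family
#'
#' Uniformly samples each member's gap layout (s - w gap slots among the
#' interior positions) and a position subset of the requested size; uses the
#' current RNG state, so results are deterministic under a fixed seed.
#'
#' @param problem A `design_problem`.
#' @return A `seed_family`.
#' @export
sample_candidate <- function(problem) {
  members <- lapply(seq_len(problem$family_size), function(i) {
    seed <- .sample_pattern(problem$w, problem$max_span)
    valid <- 0:(problem$m - seed$s)
    if (length(valid) < problem$n_positions) {
      stop(sprintf("infeasible: %d positions do not fit m=%d for span %d",
                   problem$n_positions, problem$m, seed$s), call. = FALSE)
    }
    pos <- sort(sample(valid, problem$n_positions))
    positioned_seed(seed, pos, problem$m)
  })
  seed_family(members, problem$m)
}

.design_objective <- function(problem) {
  if (problem$mode == "lossy") {
    function(fam) compute_sensitivity(fam, problem$model, problem$m)$value
  } else {
    function(fam) {
      if (!check_lossless(fam, problem$budget, problem$m)$lossless) return(-1)
      1 - background_hit_probability(fam, problem$m)   # selectivity
    }
  }
}

# Elementary moves: shift one gap of one member by one slot, or swap one
# allowed position for an unused one.
.neighbor_moves <- function(family) {
  moves <- list()
  for (mi in seq_along(family$members)) {
    mem <- family$members[[mi]]
    chars <- strsplit(mem$seed$pattern, "")[[1]]
    gaps <- which(chars == "-")
    for (g in gaps) {
      for (d in c(-1L, 1L)) {
        t <- g + d
        if (t >= 2L && t <= length(chars) - 1L && chars[t] == "#") {
          moves[[length(moves) + 1L]] <- list(member = mi, kind = "gap",
                                              from = g, to = t)
        }
      }
    }
    valid <- 0:(mem$m - mem$seed$s)
    unused <- setdiff(valid, mem$positions)
    for (p in mem$positions) {
      for (u in unused) {
        moves[[length(moves) + 1L]] <- list(member = mi, kind = "pos",
                                            from = p, to = u)
      }
    }
  }
  moves
}

.apply_move <- function(family, mv) {
  mem <- family$members[[mv$member]]
  if (mv$kind == "gap") {
    chars <- strsplit(mem$seed$pattern, "")[[1]]
    chars[mv$from] <- "#"
    chars[mv$to] <- "-"
    seed <- parse_seed(paste(chars, collapse = ""))
    mem <- positioned_seed(seed, mem$positions[mem$positions + seed$s <= mem$m],
                           mem$m)
  } else {
    pos <- sort(c(setdiff(mem$positions, mv$from), mv$to))
    mem <- positioned_seed(mem$seed, pos, mem$m)
  }
  family$members[[mv$member]] <- mem
  seed_family(family$members, family$m)
}

#' Hill-climbing local optimization of a seed family
#'
#' Repeatedly evaluates the elementary moves (shift one gap by one slot, swap
#' one allowed position for an unused one) in randomized order and accepts
#' the first strictly improving move; stops after `steps` accepted moves or
#' when no move improves.  The returned family never scores below the input.
#'
#' @param family A `seed_family`.
#' @param objective Function `seed_family -> numeric` to maximize.
#' @param steps Maximum number of accepted moves.
#' @return List with `family` (best found) and `score`; also `trace`, the
#'   non-decreasing score sequence.
#' @export
local_optimize <- function(family, objective, steps = 50L) {
  cur <- family
  cur_score <- objective(cur)
  trace <- cur_score
  for (step in seq_len(steps)) {
    if (cur_score >= 1) break
    moves <- .neighbor_moves(cur)
    if (!length(moves)) break
    moves <- moves[sample.int(length(moves))]
    improved <- FALSE
    for (mv in moves) {
      cand <- tryCatch(.apply_move(cur, mv), error = function(e) NULL)
      if (is.null(cand)) next
      sc <- objective(cand)
      if (sc > cur_score) {
        cur <- cand
        cur_score <- sc
        trace <- c(trace, sc)
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  list(family = cur, score = cur_score, trace = trace)
}

#' Run a seed-design search
#'
#' Samples `n_candidates` families, scores them (sensitivity in lossy mode;
#' in lossless mode failed certifications are discarded and survivors score
#' by selectivity), locally optimizes the `top_k` best and re-ranks.  Fully
#' reproducible given the problem's `rng_seed`.
#'
#' @param problem A `design_problem`.
#' @return Tibble ranked by decreasing score: pattern(s), positions, score,
#'   sensitivity/selectivity columns, lossless flag; attribute `families`
#'   carries the `seed_family` objects.  Zero feasible candidates give an
#'   empty tibble.
#' @export
design_seeds <- function(problem) {
  withr::local_seed(problem$rng_seed)
  objective <- .design_objective(problem)
  cands <- vector("list", problem$n_candidates)
  scores <- numeric(problem$n_candidates)
  for (i in seq_len(problem$n_candidates)) {
    cands[[i]] <- sample_candidate(problem)
    scores[i] <- objective(cands[[i]])
  }
  keep <- which(scores >= 0)
  if (!length(keep)) {
    out <- tibble::tibble(rank = integer(0), family = character(0),
                          positions = character(0), score = numeric(0),
                          background_hit = numeric(0), lossless = logical(0))
    attr(out, "families") <- list()
    attr(out, "diagnostics") <- "no feasible candidate passed certification"
    return(out)
  }
  ord <- keep[order(scores[keep], decreasing = TRUE)]
  top <- utils::head(ord, problem$top_k)
  optimized <- lapply(top, function(i) {
    local_optimize(cands[[i]], objective, problem$opt_steps)
  })
  fams <- lapply(optimized, `[[`, "family")
  fscores <- vapply(optimized, `[[`, numeric(1), "score")
  bg <- vapply(fams, function(f) background_hit_probability(f, problem$m),
               numeric(1))
  pat <- vapply(fams, function(f) {
    paste(vapply(f$members, function(x) x$seed$pattern, character(1)),
          collapse = ",")
  }, character(1))
  pos <- vapply(fams, function(f) {
    paste(vapply(f$members, function(x) paste(x$positions, collapse = ","),
                 character(1)), collapse = ";")
  }, character(1))
  lossless <- if (problem$mode == "lossless") rep(TRUE, length(fams)) else
    rep(NA, length(fams))
  # rank by score, ties by higher selectivity then pattern order
  ord2 <- order(-fscores, bg, pat)
  out <- tibble::tibble(rank = seq_along(ord2), family = pat[ord2],
                        positions = pos[ord2], score = fscores[ord2],
                        background_hit = bg[ord2], lossless = lossless[ord2])
  attr(out, "families") <- fams[ord2]
  out
}
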