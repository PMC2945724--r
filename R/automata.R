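# Deterministic automata over the alignment alphabet.
#
# Symbols are coded 1 = match ('1'), 2 = mismatch ('0'), 3 = indel ('I').
# An automaton in mode "mm" is total over symbols 1..2, in mode "mmi" over
# 1..3.  `delta` is an n x nsym integer matrix, `finals` a logical vector,
# `cost` an optional numeric matrix of per-transition costs (same shape as
# `delta`).

#' Construct an alignment DFA
#'
#' @param delta Integer matrix, states x symbols (2 columns for the
#'   match/mismatch alphabet, 3 with indels).
#' @param initial Initial state index.
#' @param finals Logical vector of final (hit) states.
#' @param mode `"mm"` or `"mmi"`.
#' @param cost Optional numeric cost matrix, same shape as `delta`.
#' @return An `alignment_dfa`.
#' @export
new_alignment_dfa <- function(delta, initial, finals,
                              mode = c("mm", "mmi"), cost = NULL) {
  mode <- match.arg(mode)
  delta <- as.matrix(delta)
  storage.mode(delta) <- "integer"
  nsym <- if (mode == "mm") 2L else 3L
  stopifnot(ncol(delta) == nsym, length(finals) == nrow(delta),
            initial >= 1, initial <= nrow(delta))
  if (any(delta < 1L | delta > nrow(delta))) {
    stop("transition function is not total over the declared states",
         call. = FALSE)
  }
  if (!is.null(cost)) stopifnot(all(dim(cost) == dim(delta)), all(cost >= 0))
  structure(list(delta = delta, initial = as.integer(initial),
                 finals = as.logical(finals), mode = mode, cost = cost),
            class = "alignment_dfa")
}

#' @export
print.alignment_dfa <- function(x, ...) {
  cat(sprintf("<alignment_dfa> %d states, mode=%s, %d final%s%s\n",
              nrow(x$delta), x$mode, sum(x$finals),
              if (sum(x$finals) == 1) "" else "s",
              if (!is.null(x$cost)) ", weighted" else ""))
  invisible(x)
}

#' Number of states of a DFA
#' @param dfa An `alignment_dfa`.
#' @return Integer.
#' @export
n_states <- function(dfa) nrow(dfa$delta)

#' Run a DFA on an alignment and test acceptance
#'
#' @param dfa An `alignment_dfa`.
#' @param alignment Alignment string over '1'/'0'/'I' or integer codes.
#' @return Logical: is the state reached after the whole string final?
#' @export
dfa_accepts <- function(dfa, alignment) {
  syms <- alignment_symbols(alignment)
  if (dfa$mode == "mm" && any(syms == 3L)) {
    stop("indel symbol fed to a match/mismatch automaton", call. = FALSE)
  }
  q <- dfa$initial
  for (s in syms) q <- dfa$delta[q, s]
  dfa$finals[q]
}

# Vectorized acceptance over a matrix of symbol strings (rows).
dfa_accepts_matrix <- function(dfa, M) {
  st <- rep.int(dfa$initial, nrow(M))
  for (j in seq_len(ncol(M))) st <- dfa$delta[cbind(st, M[, j])]
  dfa$finals[st]
}

# All strings of length m over nsym symbols, one per row (codes 1..nsym).
enumerate_strings <- function(m, nsym = 2L) {
  if (m == 0L) return(matrix(integer(0), 1, 0))
  n <- nsym^m
  if (n > 2e6) stop("enumeration too large", call. = FALSE)
  M <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    M[, j] <- rep(rep(seq_len(nsym), each = nsym^(m - j)), length.out = n)
  }
  M
}

#' Are all final states absorbing?
#' @param dfa An `alignment_dfa`.
#' @return Logical.
#' @export
finals_absorbing <- function(dfa) {
  f <- which(dfa$finals)
  all(dfa$delta[f, , drop = FALSE] == f)
}

# Redirect every transition out of a final state back to itself.
absorb_finals <- function(dfa) {
  f <- which(dfa$finals)
  dfa$delta[f, ] <- f
  if (!is.null(dfa$cost)) dfa$cost[f, ] <- 0
  dfa
}

#' Minimize a DFA (Moore partition refinement)
#'
#' @param dfa An unweighted `alignment_dfa`.
#' @return The minimal equivalent `alignment_dfa`.  The `reset` attribute
#'   (if present) is mapped through the state quotient.
#' @export
minimize_dfa <- function(dfa) {
  if (!is.null(dfa$cost)) stop("cannot minimize a weighted automaton",
                               call. = FALSE)
  n <- nrow(dfa$delta)
  nsym <- ncol(dfa$delta)
  cls <- as.integer(dfa$finals) + 1L
  nc <- length(unique(cls))
  repeat {
    parts <- vector("list", nsym + 1L)
    parts[[1]] <- cls
    for (s in seq_len(nsym)) parts[[s + 1L]] <- cls[dfa$delta[, s]]
    key <- do.call(paste, c(parts, sep = "\r"))
    cls2 <- match(key, key)
    cls2 <- match(cls2, sort(unique(cls2)))
    nc2 <- max(cls2)
    if (nc2 == nc) break
    cls <- cls2
    nc <- nc2
  }
  rep_state <- match(seq_len(nc), cls)
  delta <- matrix(0L, nc, nsym)
  for (s in seq_len(nsym)) delta[, s] <- cls[dfa$delta[rep_state, s]]
  out <- new_alignment_dfa(delta, cls[dfa$initial], dfa$finals[rep_state],
                           dfa$mode)
  if (!is.null(attr(dfa, "reset"))) attr(out, "reset") <- cls[attr(dfa, "reset")]
  attr(out, "family") <- attr(dfa, "family")
  attr(out, "chain") <- attr(dfa, "chain")
  out
}

#' Compact seed automaton over the match/mismatch alphabet
#'
#' Builds the deterministic automaton detecting occurrences of a spaced seed,
#' by subset construction over the seed-prefix NFA followed by minimization.
#' The minimal automaton never exceeds the (w+1)*2^(s-w) bound of the compact
#' construction for spaced seeds.
#'
#' @param seed A `spaced_seed` or pattern string.
#' @param style `"hit"` (default): accepts every string containing at least
#'   one seed occurrence; final state absorbing.  `"suffix"`: a state is final
#'   iff an occurrence ends at the current position (non-absorbing); this is
#'   the variant used in position products.
#' @return An `alignment_dfa` in mode `"mm"`, with attribute `reset` naming
#'   the no-partial-match state (the target of an indel reset).
#' @export
seed_to_dfa <- function(seed, style = c("hit", "suffix")) {
  style <- match.arg(style)
  if (is.character(seed)) seed <- parse_seed(seed)
  s <- seed$s
  req <- strsplit(seed$pattern, "")[[1]] == "#"
  # bit j (0-based) of a mask = "a seed prefix of length j+1 matches the
  # current suffix"; prefix length 0 is implicit.
  nbits <- s - 1L
  if (nbits > 28L) stop("seed span too large for this construction",
                        call. = FALSE)
  compat <- integer(2)     # per symbol, allowed-prefix mask over bits 0..s-2
  for (a in 1:2) {
    ok <- if (a == 1L) rep(TRUE, s) else !req
    bits <- which(ok[seq_len(nbits) + 0L])   # positions 1..s-1 of pattern
    compat[a] <- sum(bitwShiftL(1L, bits - 1L))
  }
  can_complete <- function(mask, a) {
    if (a != 1L) return(FALSE)          # last pattern char is '#'
    if (s == 1L) return(TRUE)
    bitwAnd(mask, bitwShiftL(1L, s - 2L)) != 0L
  }
  step_mask <- function(mask, a) {
    bitwAnd(bitwOr(bitwShiftL(mask, 1L), 1L), compat[a])
  }
  # states keyed by (mask, ends_now); BFS
  key_of <- function(mask, fin) paste0(mask, if (fin) "F" else "")
  env <- new.env(hash = TRUE, parent = emptyenv())
  masks <- integer(0); fins <- logical(0)
  get_id <- function(mask, fin) {
    k <- key_of(mask, fin)
    id <- env[[k]]
    if (is.null(id)) {
      id <- length(masks) + 1L
      env[[k]] <- id
      masks[[id]] <<- mask
      fins[[id]] <<- fin
    }
    id
  }
  init <- get_id(0L, FALSE)
  if (style == "hit") accept <- NA_integer_
  trans <- list()
  i <- 1L
  while (i <= length(masks)) {
    if (style == "hit" && fins[i]) { i <- i + 1L; next }
    row <- integer(2)
    for (a in 1:2) {
      complete <- can_complete(masks[i], a)
      nm <- step_mask(masks[i], a)
      if (style == "hit" && complete) {
        if (is.na(accept)) accept <- get_id(-1L, TRUE)
        row[a] <- accept
      } else {
        row[a] <- get_id(nm, complete && style == "suffix")
      }
    }
    trans[[i]] <- row
    i <- i + 1L
  }
  n <- length(masks)
  delta <- matrix(0L, n, 2)
  for (q in seq_len(n)) {
    if (style == "hit" && fins[q]) delta[q, ] <- q else delta[q, ] <- trans[[q]]
  }
  dfa <- new_alignment_dfa(delta, init, fins, "mm")
  attr(dfa, "reset") <- env[["0"]]
  minimize_dfa(dfa)
}

#' Linear position-chain automaton
#'
#' A chain of m+1 states counting consumed symbols; state q_i is final iff
#' i - s belongs to the allowed start-position set P, i.e. a seed occurrence
#' of span s ending at position i started at an allowed offset.
#'
#' @param m Read length.
#' @param s Seed span.
#' @param P Integer vector of allowed 0-based start offsets (p + s <= m).
#' @param mode `"mm"` or `"mmi"`.  The chain counts read positions, so in
#'   mode `"mmi"` an indel symbol (a color inserted or deleted between read
#'   positions) does not advance it.
#' @return An `alignment_dfa` whose last state self-loops.
#' @export
position_chain <- function(m, s, P, mode = c("mm", "mmi")) {
  mode <- match.arg(mode)
  P <- as.integer(P)
  if (length(P) && any(P < 0L | P + s > m)) {
    stop("positions must satisfy 0 <= p and p + s <= m", call. = FALSE)
  }
  if (!length(P)) {
    warning("empty position set: chain automaton has no final state")
  }
  n <- m + 1L
  nxt <- c(seq_len(m) + 1L, n)            # q_m self-loops
  nsym <- if (mode == "mm") 2L else 3L
  delta <- matrix(rep(nxt, nsym), n, nsym)
  if (mode == "mmi") delta[, 3L] <- seq_len(n)   # indels consume no position
  finals <- (seq_len(n) - 1L - s) %in% P
  dfa <- new_alignment_dfa(delta, 1L, finals, mode)
  attr(dfa, "chain") <- TRUE
  dfa
}

#' Synchronous product of two alignment DFAs
#'
#' Builds the reachable part of the standard product; finals are combined by
#' `final_rule`.  With a suffix-style seed automaton, a position chain and
#' `final_rule = "AND"`, `absorb = TRUE`, the result accepts exactly the
#' strings (of length <= m) in which some seed occurrence starts at an
#' allowed position.
#'
#' @param a,b `alignment_dfa`s in the same mode.
#' @param final_rule `"AND"` or `"OR"`.
#' @param absorb Make product finals absorbing (hit semantics).
#' @return An `alignment_dfa`.  Costs, if present on either factor, are added.
#' @export
dfa_product <- function(a, b, final_rule = c("AND", "OR"), absorb = FALSE) {
  final_rule <- match.arg(final_rule)
  if (a$mode != b$mode) stop("alphabet modes differ", call. = FALSE)
  na <- nrow(a$delta); nb <- nrow(b$delta)
  nsym <- ncol(a$delta)
  if (as.double(na) * nb > 2e7) stop("product state space too large",
                                     call. = FALSE)
  idmap <- integer(na * nb)                # pair code -> state id (0 = unseen)
  code <- function(ia, ib) (ia - 1L) * nb + ib
  pairs_a <- integer(0); pairs_b <- integer(0)
  add <- function(ia, ib) {
    cd <- code(ia, ib)
    id <- idmap[cd]
    if (id == 0L) {
      id <- length(pairs_a) + 1L
      idmap[cd] <<- id
      pairs_a[[id]] <<- ia
      pairs_b[[id]] <<- ib
    }
    id
  }
  init <- add(a$initial, b$initial)
  want_cost <- !is.null(a$cost) || !is.null(b$cost)
  delta_rows <- list(); cost_rows <- if (want_cost) list() else NULL
  fin_of <- function(ia, ib) {
    if (final_rule == "AND") a$finals[ia] && b$finals[ib]
    else a$finals[ia] || b$finals[ib]
  }
  q <- 1L
  while (q <= length(pairs_a)) {
    ia <- pairs_a[q]; ib <- pairs_b[q]
    if (absorb && fin_of(ia, ib)) {
      delta_rows[[q]] <- rep.int(q, nsym)
      if (want_cost) cost_rows[[q]] <- numeric(nsym)
    } else {
      row <- integer(nsym); crow <- numeric(nsym)
      for (s in seq_len(nsym)) {
        row[s] <- add(a$delta[ia, s], b$delta[ib, s])
        if (want_cost) {
          crow[s] <- (if (is.null(a$cost)) 0 else a$cost[ia, s]) +
            (if (is.null(b$cost)) 0 else b$cost[ib, s])
        }
      }
      delta_rows[[q]] <- row
      if (want_cost) cost_rows[[q]] <- crow
    }
    q <- q + 1L
  }
  n <- length(pairs_a)
  delta <- do.call(rbind, delta_rows)
  finals <- mapply(fin_of, pairs_a, pairs_b)
  cost <- if (want_cost) do.call(rbind, cost_rows) else NULL
  out <- new_alignment_dfa(delta, init, finals, a$mode, cost)
  attr(out, "pair_a") <- pairs_a
  attr(out, "pair_b") <- pairs_b
  out
}

#' Hit automaton of a position-restricted seed family
#'
#' Accepts the strings of length <= m in which at least one member seed hits
#' at one of its allowed positions; the final state is absorbing.  Built
#' directly over the placements of the family: a state records, for every
#' placement window overlapping the current read position, whether it is
#' still viable.  Positions are read coordinates: in mode `"mmi"` an indel
#' symbol (a color inserted or deleted between read positions) does not
#' advance the position but kills every placement already in progress --
#' seeds must sit between indels, while placements starting at or after the
#' current position are unaffected.
#'
#' @param family A `seed_family`.
#' @param mode `"mm"` (match/mismatch) or `"mmi"` (with indels).
#' @param minimize Minimize the result (default TRUE).
#' @return An `alignment_dfa` with attribute `family` (enabling
#'   [indel_extend()] to rebuild it over the 3-symbol alphabet).
#' @export
family_to_dfa <- function(family, mode = c("mm", "mmi"), minimize = TRUE) {
  mode <- match.arg(mode)
  m <- family$m
  starts <- integer(0); ends <- integer(0); reqs <- list()
  for (mem in family$members) {
    rq <- strsplit(mem$seed$pattern, "")[[1]] == "#"
    for (p in mem$positions) {
      starts <- c(starts, p)
      ends <- c(ends, p + mem$seed$s - 1L)
      reqs[[length(reqs) + 1L]] <- rq
    }
  }
  np <- length(starts)
  nsym <- if (mode == "mm") 2L else 3L
  # placements in progress before reading position i (0-based): p < i <= end
  prog <- vector("list", m + 1L)
  strt <- vector("list", m)
  for (i in 0:m) prog[[i + 1L]] <- which(starts < i & ends >= i)
  for (i in 0:(m - 1L)) strt[[i + 1L]] <- which(starts == i)

  env <- new.env(hash = TRUE, parent = emptyenv())
  st_pos <- integer(0); st_alive <- list()
  get_id <- function(i, alive) {
    k <- paste0(i, ":", paste(alive, collapse = ","))
    id <- env[[k]]
    if (is.null(id)) {
      id <- length(st_pos) + 1L
      env[[k]] <- id
      st_pos[[id]] <<- i
      st_alive[[id]] <<- alive
    }
    id
  }
  ACCEPT <- get_id(-1L, integer(0))       # absorbing final
  DEAD <- get_id(-2L, integer(0))         # absorbing non-final sink
  init <- get_id(0L, integer(0))
  delta_rows <- list()
  delta_rows[[ACCEPT]] <- rep.int(ACCEPT, nsym)
  delta_rows[[DEAD]] <- rep.int(DEAD, nsym)
  q <- init
  while (q <= length(st_pos)) {
    if (q == ACCEPT || q == DEAD) { q <- q + 1L; next }
    i <- st_pos[q]
    if (i >= m) {
      row <- rep.int(DEAD, nsym)
      if (nsym == 3L) row[3L] <- get_id(i, integer(0))  # trailing indels
      delta_rows[[q]] <- row
      q <- q + 1L
      next
    }
    cand <- c(st_alive[[q]], strt[[i + 1L]])
    row <- integer(nsym)
    for (a in seq_len(nsym)) {
      if (a == 3L) {
        # indel between read positions i-1 and i: kills every placement in
        # progress, consumes no read position
        row[a] <- get_id(i, integer(0))
        next
      }
      surv <- if (a == 1L) cand else {
        keep <- !vapply(cand, function(pl) reqs[[pl]][i - starts[pl] + 1L],
                        logical(1))
        cand[keep]
      }
      if (any(ends[surv] == i)) {
        row[a] <- ACCEPT
      } else {
        alive <- surv[ends[surv] > i]
        row[a] <- get_id(i + 1L, sort(alive))
      }
    }
    delta_rows[[q]] <- row
    q <- q + 1L
  }
  n <- length(st_pos)
  delta <- do.call(rbind, delta_rows)
  finals <- seq_len(n) == ACCEPT
  dfa <- new_alignment_dfa(delta, init, finals, mode)
  attr(dfa, "family") <- family
  if (minimize) {
    dfa <- minimize_dfa(dfa)
  } else {
    attr(dfa, "pos") <- st_pos        # read position per state (-1 accept,
  }                                   # -2 dead); dropped by minimization
  attr(dfa, "family") <- family
  dfa
}

#' Extend a match/mismatch automaton with an indel symbol
#'
#' The indel symbol acts as a hard reset of all partial seed matches: no seed
#' window may span an indel.  For automata built by [family_to_dfa()] the
#' extension is exact (the automaton is rebuilt over the 3-symbol alphabet,
#' keeping the position bookkeeping).  For plain seed automata the indel
#' transition of every non-absorbing state goes to the no-partial-match
#' state; for position chains the indel advances the chain like any symbol.
#'
#' @param a An `alignment_dfa` in mode `"mm"`.
#' @return An `alignment_dfa` in mode `"mmi"` agreeing with `a` on
#'   indel-free strings.
#' @export
indel_extend <- function(a) {
  if (a$mode == "mmi") return(a)
  fam <- attr(a, "family")
  if (!is.null(fam)) return(family_to_dfa(fam, mode = "mmi"))
  if (isTRUE(attr(a, "chain"))) {
    delta <- cbind(a$delta, a$delta[, 1L])
    out <- new_alignment_dfa(delta, a$initial, a$finals, "mmi")
    attr(out, "chain") <- TRUE
    return(out)
  }
  reset <- attr(a, "reset")
  if (is.null(reset)) {
    stop("cannot indel-extend: automaton has no reset state or family metadata",
         call. = FALSE)
  }
  n <- nrow(a$delta)
  absorbing <- rowSums(a$delta == seq_len(n)) == ncol(a$delta)
  indel_col <- ifelse(a$finals & absorbing, seq_len(n), reset)
  out <- new_alignment_dfa(cbind(a$delta, as.integer(indel_col)),
                           a$initial, a$finals, "mmi")
  attr(out, "reset") <- reset
  out
}

# ---- dump / load ------------------------------------------------------------

#' Write an automaton as a plain-text transition table
#'
#' One line per transition: `state symbol state [cost]`, with `@` prefixed to
#' the initial state and `*` to final states wherever they appear.
#'
#' @param dfa An `alignment_dfa`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
dfa_write <- function(dfa, path) {
  tag <- function(q) {
    paste0(if (q == dfa$initial) "@" else "",
           if (dfa$finals[q]) "*" else "", q)
  }
  lines <- c(sprintf("; mode=%s states=%d", dfa$mode, nrow(dfa$delta)))
  for (q in seq_len(nrow(dfa$delta))) {
    for (s in seq_len(ncol(dfa$delta))) {
      ln <- paste(tag(q), ALIGN_CHARS[s], tag(dfa$delta[q, s]))
      if (!is.null(dfa$cost)) ln <- paste(ln, dfa$cost[q, s])
      lines <- c(lines, ln)
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an automaton from the transition-table format
#'
#' @param path Path written by [dfa_write()].
#' @return An `alignment_dfa`.
#' @export
dfa_read <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, ";")][1]
  mode <- sub(".*mode=(\\w+).*", "\\1", meta)
  lines <- lines[!startsWith(lines, ";") & nzchar(lines)]
  parts <- strsplit(trimws(lines), "\\s+")
  parse_state <- function(tok) {
    init <- grepl("@", tok, fixed = TRUE)
    fin <- grepl("*", tok, fixed = TRUE)
    list(q = as.integer(gsub("[@*]", "", tok)), init = init, fin = fin)
  }
  n <- 0L; initial <- NA_integer_
  rows <- lapply(parts, function(p) {
    from <- parse_state(p[1]); to <- parse_state(p[3])
    list(from = from, sym = match(p[2], ALIGN_CHARS), to = to,
         cost = if (length(p) >= 4) as.numeric(p[4]) else NA_real_)
  })
  for (r in rows) n <- max(n, r$from$q, r$to$q)
  nsym <- if (mode == "mm") 2L else 3L
  delta <- matrix(1L, n, nsym)
  finals <- logical(n)
  has_cost <- any(!is.na(vapply(rows, `[[`, numeric(1), "cost")))
  cost <- if (has_cost) matrix(0, n, nsym) else NULL
  for (r in rows) {
    delta[r$from$q, r$sym] <- r$to$q
    if (r$from$fin) finals[r$from$q] <- TRUE
    if (r$to$fin) finals[r$to$q] <- TRUE
    if (r$from$init) initial <- r$from$q
    if (r$to$init) initial <- if (is.na(initial)) r$to$q else initial
    if (has_cost && !is.na(r$cost)) cost[r$from$q, r$sym] <- r$cost
  }
  if (is.na(initial)) stop("no initial state marked with '@'", call. = FALSE)
  new_alignment_dfa(delta, initial, finals, mode, cost)
}

# ---- NFA determinization (used by the budget automata) ---------------------

# nfa: list(n, init = integer vector, finals = logical(n),
#           trans = list over states of list over symbols of integer vectors)
determinize_nfa <- function(nfa, nsym, mode) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  sets <- list()
  get_id <- function(set) {
    k <- paste0("s", paste(set, collapse = ","))
    id <- env[[k]]
    if (is.null(id)) {
      id <- length(sets) + 1L
      env[[k]] <- id
      sets[[id]] <<- set
    }
    id
  }
  init <- get_id(sort(unique(nfa$init)))
  delta_rows <- list()
  q <- 1L
  while (q <= length(sets)) {
    row <- integer(nsym)
    for (s in seq_len(nsym)) {
      tgt <- sort(unique(unlist(lapply(sets[[q]], function(u) nfa$trans[[u]][[s]]))))
      row[s] <- get_id(tgt)
    }
    delta_rows[[q]] <- row
    q <- q + 1L
  }
  n <- length(sets)
  finals <- vapply(sets, function(set) any(nfa$finals[set]), logical(1))
  new_alignment_dfa(do.call(rbind, delta_rows), init, finals, mode)
}
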