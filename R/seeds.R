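# Spaced seeds, position-restricted seeds and seed families.
#
# A spaced seed is a pattern over '#' (required color match) and '-'
# (don't-care), starting and ending with '#'.  Its weight w is the number of
# '#' and its span s the pattern length.  A position-restricted seed pairs a
# seed with the sorted set of 0-based read offsets where it is allowed to
# hit; a family is a non-empty list of positioned seeds sharing a read
# length m.

#' Parse a spaced-seed pattern
#'
#' Whitespace inside the pattern (as in printed seed tables) is deleted before
#' parsing.
#'
#' @param text Pattern string over '#', '-' and whitespace.
#' @return A `spaced_seed`: list with `pattern`, `w` (weight), `s` (span).
#' @examples
#' parse_seed("####-##-####")  # weight 10, span 12
#' @export
parse_seed <- function(text) {
  stopifnot(length(text) == 1)
  pat <- gsub("\\s+", "", text)
  if (!nzchar(pat)) stop("empty seed pattern", call. = FALSE)
  chars <- strsplit(pat, "")[[1]]
  bad <- which(!chars %in% c("#", "-"))
  if (length(bad)) {
    stop(sprintf("invalid seed character '%s' at position %d", chars[bad[1]],
                 bad[1]), call. = FALSE)
  }
  if (chars[1] != "#" || chars[length(chars)] != "#") {
    stop("seed pattern must start and end with '#'", call. = FALSE)
  }
  structure(list(pattern = pat, w = sum(chars == "#"), s = length(chars)),
            class = "spaced_seed")
}

#' @export
format.spaced_seed <- function(x, ...) x$pattern

#' @export
print.spaced_seed <- function(x, ...) {
  cat(sprintf("<spaced_seed> %s  (w=%d, s=%d)\n", x$pattern, x$w, x$s))
  invisible(x)
}

#' Attach allowed start positions to a seed
#'
#' @param seed A `spaced_seed` or pattern string.
#' @param positions Sorted 0-based start offsets on the read, or `"*"` /
#'   `NULL` together with `m` for all valid positions `0..m-s`.  An empty set
#'   is legal: such a seed never hits (sensitivity 0, never lossless for any
#'   budget >= 0).
#' @param m Read length; required to validate positions (p + s <= m) and to
#'   expand `"*"`.
#' @return A `positioned_seed`.
#' @export
positioned_seed <- function(seed, positions = "*", m) {
  if (is.character(seed)) seed <- parse_seed(seed)
  stopifnot(inherits(seed, "spaced_seed"), !missing(m))
  if (is.null(positions) || identical(positions, "*")) {
    if (m < seed$s) stop("read length smaller than seed span", call. = FALSE)
    positions <- 0:(m - seed$s)
  }
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) && (min(positions) < 0 || any(positions + seed$s > m))) {
    stop(sprintf("positions must satisfy 0 <= p and p + s <= m (s=%d, m=%d)",
                 seed$s, m), call. = FALSE)
  }
  structure(list(seed = seed, positions = positions, m = as.integer(m)),
            class = "positioned_seed")
}

#' @export
print.positioned_seed <- function(x, ...) {
  cat(sprintf("<positioned_seed> %s  @ {%s}  (m=%d)\n", x$seed$pattern,
              paste(x$positions, collapse = ","), x$m))
  invisible(x)
}

#' Build a seed family
#'
#' @param members List of `positioned_seed`s (all with the same read length),
#'   or of `spaced_seed`s/pattern strings (placed at all valid positions).
#' @param m Read length.
#' @return A `seed_family`.
#' @export
seed_family <- function(members, m) {
  if (inherits(members, "positioned_seed") || inherits(members, "spaced_seed") ||
      is.character(members)) {
    members <- list(members)
  }
  members <- lapply(members, function(x) {
    if (inherits(x, "positioned_seed")) {
      if (x$m != m) stop("member read length differs from family m", call. = FALSE)
      x
    } else positioned_seed(x, "*", m)
  })
  if (!length(members)) stop("a seed family must be non-empty", call. = FALSE)
  structure(list(members = members, m = as.integer(m)), class = "seed_family")
}

#' @export
print.seed_family <- function(x, ...) {
  cat(sprintf("<seed_family> %d member(s), m=%d\n", length(x$members), x$m))
  for (mem in x$members) {
    cat(sprintf("  %s @ {%s}\n", mem$seed$pattern,
                paste(mem$positions, collapse = ",")))
  }
  invisible(x)
}

# ---- alignment strings ------------------------------------------------------

# Alignment symbols: internally 1 = match, 2 = mismatch, 3 = indel;
# printed '1', '0', 'I'.
ALIGN_CHARS <- c("1", "0", "I")

#' Convert a printed alignment string to internal symbol codes
#'
#' @param x String over '1' (match), '0' (mismatch), 'I' (indel), or an
#'   integer vector already in codes 1..3.
#' @return Integer vector of symbol codes.
#' @export
alignment_symbols <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    stopifnot(all(x %in% 1:3))
    return(x)
  }
  chars <- strsplit(x, "")[[1]]
  codes <- match(chars, ALIGN_CHARS)
  if (anyNA(codes)) {
    stop(sprintf("invalid alignment symbol '%s'", chars[which(is.na(codes))[1]]),
         call. = FALSE)
  }
  codes
}

#' Does a seed hit an alignment at a given offset?
#'
#' A hit requires the match symbol under every '#'; '-' positions are
#' unconstrained except that an indel symbol anywhere under the window (at
#' '#' or '-') forbids the hit: seeds must be placed between indels.
#'
#' @param seed A `spaced_seed` or pattern string.
#' @param alignment Alignment string over '1'/'0'/'I' or integer codes.
#' @param offset 0-based start offset of the window.
#' @return Logical scalar.
#' @export
seed_hits <- function(seed, alignment, offset) {
  if (is.character(seed)) seed <- parse_seed(seed)
  al <- alignment_symbols(alignment)
  if (offset < 0 || offset + seed$s > length(al)) {
    stop("offset out of range for this alignment", call. = FALSE)
  }
  win <- al[(offset + 1):(offset + seed$s)]
  if (any(win == 3L)) return(FALSE)
  req <- strsplit(seed$pattern, "")[[1]] == "#"
  all(win[req] == 1L)
}

#' Does a seed family hit an alignment?
#'
#' Direct scan over all allowed placements of all members (used as the
#' brute-force oracle for the automaton route).  Allowed positions are read
#' coordinates: indel columns do not consume a read position, so a window is
#' checked at the column where its start position sits, must be free of
#' indel columns, and must satisfy the member's '#' requirements.
#'
#' @param family A `seed_family`.
#' @param alignment Alignment string/codes with `family$m` non-indel columns
#'   (or fewer -- windows that do not fit cannot hit).
#' @return Logical scalar.
#' @export
family_hits <- function(family, alignment) {
  al <- alignment_symbols(alignment)
  is_ind <- al == 3L
  readpos <- cumsum(!is_ind) - 1L    # read coordinate of each column
  nc <- length(al)
  for (mem in family$members) {
    s <- mem$seed$s
    req <- strsplit(mem$seed$pattern, "")[[1]] == "#"
    if (s > nc) next
    for (cc in seq_len(nc - s + 1L)) {
      if (is_ind[cc]) next
      if (!(readpos[cc] %in% mem$positions)) next
      win <- al[cc:(cc + s - 1L)]
      if (any(win == 3L)) next
      if (all(win[req] == 1L)) return(TRUE)
    }
  }
  FALSE
}

#' Maximal number of overlapping seed placements
#'
#' Each placement of a member at an allowed position spans an interval of s
#' read positions; the chromatic number of the interval graph of all
#' placements equals (for interval graphs) the maximum number of placements
#' covering any single read position.
#'
#' @param family A `seed_family`.
#' @return Integer overlap depth (0 for an all-empty-position family).
#' @export
overlap_depth <- function(family) {
  cover <- integer(family$m)
  for (mem in family$members) {
    for (p in mem$positions) {
      idx <- (p + 1):(p + mem$seed$s)
      cover[idx] <- cover[idx] + 1L
    }
  }
  if (length(cover)) max(cover) else 0L
}

# ---- seed files -------------------------------------------------------------

#' Read a seed-family file
#'
#' One family per file.  Each non-comment line is `PATTERN<TAB>positions`
#' where positions are comma-separated 0-based offsets or `*` for all valid
#' positions; lines starting with ';' are comments.
#'
#' @param path File path.
#' @param m Read length used to validate/expand positions.
#' @return A `seed_family`.
#' @export
read_seed_file <- function(path, m) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, ";")]
  if (!length(lines)) stop("seed file contains no seeds", call. = FALSE)
  members <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "\t")[[1]]
    if (length(parts) < 1 || length(parts) > 2) {
      stop(sprintf("seed file line %d: expected 'PATTERN<TAB>positions'", i),
           call. = FALSE)
    }
    pos <- if (length(parts) == 1 || parts[2] == "*") "*" else
      as.integer(strsplit(parts[2], ",")[[1]])
    positioned_seed(parse_seed(parts[1]), pos, m)
  })
  seed_family(members, m)
}

#' Write a seed family to a seed file
#'
#' @param family A `seed_family`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_seed_file <- function(family, path) {
  lines <- vapply(family$members, function(mem) {
    allpos <- 0:(mem$m - mem$seed$s)
    pos <- if (identical(mem$positions, allpos)) "*" else
      paste(mem$positions, collapse = ",")
    paste0(mem$seed$pattern, "\t", pos)
  }, character(1))
  writeLines(c(sprintf("; seed family, m=%d", family$m), lines), path)
  invisible(path)
}
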