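# 2-bit base codes of the SOLiD dibase scheme: A=0, C=1, G=2, T=3.
# The color of a dimer (b1, b2) is code(b1) XOR code(b2).  This table has the
# defining properties of the SOLiD code: identical bases give color 0, a
# single base substitution changes exactly the two colors adjacent to the
# base (one color when the base is the last one), and a read decodes
# unambiguously given its primer base.
.base_code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
.code_base <- c("A", "C", "G", "T")

.check_bases <- function(bases, what = "sequence") {
  codes <- .base_code[bases]
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1]
    stop(sprintf("non-ACGT character '%s' in %s at position %d",
                 bases[bad], what, bad), call. = FALSE)
  }
  unname(codes)
}

#' Encode a nucleotide sequence into SOLiD color space
#'
#' A read is represented by a primer base followed by the sequence of
#' overlapping dimer codes: color l encodes the pair (previous base, current
#' base), with the primer base paired to the first base.  Under this code a
#' single base substitution changes exactly two adjacent colors (one color if
#' the base is the last one).
#'
#' @param bases Character scalar over A/C/G/T, or a character vector of single
#'   bases.
#' @param primer_base Single base, one of A/C/G/T.
#' @param qualities Optional integer vector of Phred-style qualities, one per
#'   color.
#' @return A `color_read` object: list with `colors` (integer vector over
#'   0..3), `primer_base`, and optional `qualities`.
#' @examples
#' encode_to_colors("GATTACA", "T")
#' @export
encode_to_colors <- function(bases, primer_base, qualities = NULL) {
  if (length(bases) == 1 && nchar(bases[1]) != 1) {
    bases <- strsplit(toupper(bases), "")[[1]]
  } else {
    bases <- toupper(bases)
  }
  if (length(bases) == 0) stop("empty base sequence", call. = FALSE)
  stopifnot(length(primer_base) == 1)
  pcode <- .check_bases(toupper(primer_base), "primer")
  codes <- .check_bases(bases, "base sequence")
  colors <- bitwXor(c(pcode, codes[-length(codes)]), codes)
  new_color_read(colors, toupper(primer_base), qualities)
}

#' Construct a color read
#'
#' @param colors Integer vector over 0..3.
#' @param primer_base Single base A/C/G/T.
#' @param qualities Optional non-negative integer vector, same length.
#' @return A `color_read` object.
#' @export
new_color_read <- function(colors, primer_base = "T", qualities = NULL) {
  colors <- as.integer(colors)
  if (length(colors) && (anyNA(colors) || any(colors < 0L | colors > 3L))) {
    stop("colors must be integers in 0..3", call. = FALSE)
  }
  .check_bases(toupper(primer_base), "primer")
  if (!is.null(qualities)) {
    qualities <- as.integer(qualities)
    if (length(qualities) != length(colors)) {
      stop("qualities must have the same length as colors", call. = FALSE)
    }
    if (length(qualities) && any(qualities < 0L)) {
      stop("qualities must be non-negative", call. = FALSE)
    }
  }
  structure(list(colors = colors, primer_base = toupper(primer_base),
                 qualities = qualities),
            class = "color_read")
}

#' @export
print.color_read <- function(x, ...) {
  cat(sprintf("<color_read> m=%d  %s%s\n", length(x$colors), x$primer_base,
              paste(x$colors, collapse = "")))
  invisible(x)
}

#' @export
length.color_read <- function(x) length(x$colors)

#' Decode a color read back to nucleotides
#'
#' Inverse of [encode_to_colors()]: each color XORed with the code of the
#' previous base gives the current base, starting from the primer base.  A
#' single flipped color corrupts every decoded base from that position on,
#' which is the error-propagation property of the overlapping-dimer code.
#'
#' @param read A `color_read`.
#' @return Nucleotide string (empty colors give an empty string).
#' @export
decode_from_colors <- function(read) {
  stopifnot(inherits(read, "color_read"))
  if (length(read$colors) == 0) return("")
  codes <- Reduce(bitwXor, read$colors,
                  accumulate = TRUE, init = .base_code[[read$primer_base]])[-1]
  paste(.code_base[codes + 1L], collapse = "")
}

#' Convert a Phred-style quality to an error probability
#'
#' Q = -10 log10(p) hence p = 10^(-Q/10).
#'
#' @param Q Non-negative quality value(s).
#' @return Error probabilities in (0, 1].
#' @export
quality_to_error_prob <- function(Q) {
  if (any(Q < 0)) stop("quality values must be non-negative", call. = FALSE)
  10^(-Q / 10)
}

#' Quality autocorrelation along read positions
#'
#' Computes, for each lag i, the empirical correlation
#' c(i) = E((Q_j - Qbar)(Q_{j+i} - Qbar)) / sigma_Q^2 with the mean and
#' standard deviation pooled over all positions of all reads.  SOLiD reads
#' show elevated correlations at lags that are multiples of 5, an artifact of
#' the 5-round ligation chemistry.
#'
#' @param qualities Matrix (reads x positions) of quality values, a list of
#'   equal-length quality vectors, or a list of `color_read`s with qualities.
#' @param lags Integer lags to evaluate (default all 1..m-1).
#' @return Tibble with columns `lag` and `c`; attributes `mean_quality` and
#'   `sd_quality`.
#' @export
quality_correlation <- function(qualities, lags = NULL) {
  Q <- .as_quality_matrix(qualities)
  m <- ncol(Q)
  if (m < 2) stop("reads must have at least 2 positions", call. = FALSE)
  if (is.null(lags)) lags <- seq_len(m - 1)
  if (any(lags < 1 | lags > m - 1)) stop("lags must lie in 1..m-1", call. = FALSE)
  qbar <- mean(Q)
  s2 <- mean((Q - qbar)^2)
  if (s2 == 0) stop("constant qualities: zero variance, correlation undefined",
                    call. = FALSE)
  D <- Q - qbar
  cvals <- vapply(lags, function(i) {
    j <- seq_len(m - i)
    mean(D[, j, drop = FALSE] * D[, j + i, drop = FALSE])
  }, numeric(1)) / s2
  out <- tibble::tibble(lag = as.integer(lags), c = cvals)
  attr(out, "mean_quality") <- qbar
  attr(out, "sd_quality") <- sqrt(s2)
  out
}

.as_quality_matrix <- function(qualities) {
  if (is.matrix(qualities)) return(qualities)
  if (is.list(qualities)) {
    qs <- lapply(qualities, function(r) {
      if (inherits(r, "color_read")) {
        if (is.null(r$qualities)) stop("read without qualities", call. = FALSE)
        r$qualities
      } else r
    })
    lens <- lengths(qs)
    if (length(unique(lens)) != 1) stop("reads must all have the same length",
                                        call. = FALSE)
    return(do.call(rbind, qs))
  }
  stop("qualities must be a matrix or a list", call. = FALSE)
}

#' Simulate synthetic quality strings with period-5 correlation
#'
#' Quality at position l is q_mean plus a shared per-phase effect (phase =
#' l mod 5, redrawn per read) and independent noise, split so that the
#' theoretical autocorrelation at lags that are multiples of 5 equals `rho`.
#' Used to emulate the periodic quality structure of SOLiD reads.
#'
#' @param n_reads,m Number of reads and read length.
#' @param rho Target correlation at lag-5 multiples, in [0, 1).
#' @param q_mean Mean quality; either a scalar or a length-m profile.
#' @param q_sd Total quality standard deviation.
#' @param rng_seed Mandatory integer seed.
#' @return Integer matrix (n_reads x m).
#' @export
simulate_quality_matrix <- function(n_reads, m, rho = 0.6, q_mean = 25,
                                    q_sd = 6, rng_seed) {
  stopifnot(rho >= 0, rho < 1, !missing(rng_seed))
  withr::local_seed(rng_seed)
  a <- q_sd * sqrt(rho)
  b <- q_sd * sqrt(1 - rho)
  mu <- rep_len(q_mean, m)
  phase <- (seq_len(m) - 1L) %% 5L
  Q <- matrix(0L, n_reads, m)
  z <- matrix(stats::rnorm(n_reads * 5), n_reads, 5)
  eps <- matrix(stats::rnorm(n_reads * m), n_reads, m)
  Qr <- rep(mu, each = n_reads) + a * z[, phase + 1L] + b * eps
  Q[] <- pmax(1L, as.integer(round(Qr)))
  Q
}

#' Default color-read simulation parameters
#'
#' SNP probability 0.0085, indel probability 0.0015, baseline reading-error
#' probability rising linearly from 0.01 at the first position to 0.1 at the
#' last, periodic reading-error probability 0.02, indel preceded by a color
#' mismatch with probability 0.75, lag-5 quality correlation 0.6.
#'
#' @return Named list of parameters.
#' @export
default_read_params <- function() {
  list(p_snp = 0.0085, p_indel = 0.0015,
       err_start = 0.01, err_end = 0.1, p_err_periodic = 0.02,
       p_pre_indel_mismatch = 0.75, lag5_rho = 0.6,
       q_sd = 6)
}

#' Per-position reading-error probability profile
#'
#' Baseline linear interpolation between `err_start` and `err_end` plus the
#' periodic elevation `p_err_periodic` at positions whose phase (0-based
#' position mod 5) equals `phase`.
#'
#' @param m Read length.
#' @param params Parameter list as from [default_read_params()].
#' @param phase Elevated phase in 0..4.
#' @return Numeric vector of length `m`.
#' @export
read_error_profile <- function(m, params = default_read_params(), phase = 0L) {
  base <- if (m == 1) params$err_start else
    params$err_start + (params$err_end - params$err_start) *
      (seq_len(m) - 1) / (m - 1)
  per <- ifelse(((seq_len(m) - 1L) %% 5L) == phase, params$p_err_periodic, 0)
  pmin(base + per, 0.95)
}

#' Simulate SOLiD color reads from a reference
#'
#' Draws `n_reads` loci uniformly from the forward strand, takes the reference
#' color sequence at each locus, then injects, in this order: SNPs (each
#' realized as the same XOR applied to two adjacent colors, or one color at
#' the read end), color indels (deletion or insertion of one color, preceded
#' by a forced color mismatch with probability `p_pre_indel_mismatch`), and
#' reading errors at the per-position rate of [read_error_profile()] (rising
#' along the read, elevated every 5th position).  Qualities carry the period-5
#' correlation structure of [simulate_quality_matrix()] around the profile
#' -10*log10(p) of the local error rate.
#'
#' @param reference Nucleotide string (length >= m + 1).
#' @param n_reads Number of reads.
#' @param m Read length in colors.
#' @param params Parameter list, see [default_read_params()].
#' @param rng_seed Mandatory integer seed; output is deterministic given it.
#' @return Tibble with columns `id`, `locus` (0-based start base on the
#'   forward strand), `read` (list of `color_read` with qualities), and
#'   `n_snp`, `n_indel`, `n_err` event counts.
#' @export
simulate_reads <- function(reference, n_reads, m, params = default_read_params(),
                           rng_seed) {
  stopifnot(!missing(rng_seed))
  ref <- strsplit(toupper(reference), "")[[1]]
  # indel deletions consume extra reference colors; keep a buffer
  buffer <- 8L
  if (length(ref) < m + 1 + buffer) {
    stop(sprintf("reference too short: need at least %d bases for m=%d",
                 m + 1 + buffer, m), call. = FALSE)
  }
  withr::local_seed(rng_seed)
  codes <- .check_bases(ref, "reference")
  ref_colors <- bitwXor(codes[-length(codes)], codes[-1])
  err_p <- read_error_profile(m, params)
  qbase <- -10 * log10(pmin(pmax(err_p, 1e-4), 0.5))
  max_locus <- length(ref) - 1L - (m + buffer)
  loci <- sample.int(max_locus + 1L, n_reads, replace = TRUE) - 1L

  a <- params$q_sd * sqrt(params$lag5_rho)
  b <- params$q_sd * sqrt(1 - params$lag5_rho)
  phase <- (seq_len(m) - 1L) %% 5L

  reads <- vector("list", n_reads)
  n_snp <- n_indel <- n_err <- integer(n_reads)
  for (r in seq_len(n_reads)) {
    t0 <- loci[r]
    cols <- ref_colors[(t0 + 1L):(t0 + m + buffer)]
    # SNPs: substitution of base t0+l flips colors l and l+1 by the same XOR
    snp_at <- which(stats::runif(m) < params$p_snp)
    for (l in snp_at) {
      d <- sample(1:3, 1)
      cols[l] <- bitwXor(cols[l], d)
      if (l < length(cols)) cols[l + 1L] <- bitwXor(cols[l + 1L], d)
    }
    # color indels, optionally preceded by a forced color mismatch
    ind_at <- which(stats::runif(m) < params$p_indel)
    shift <- 0L
    for (l in ind_at) {
      pos <- l + shift
      if (pos < 1L || pos >= length(cols) - 1L) next
      if (stats::runif(1) < params$p_pre_indel_mismatch) {
        cols[pos] <- (cols[pos] + sample(1:3, 1)) %% 4L
      }
      if (stats::runif(1) < 0.5) {
        cols <- cols[-(pos + 1L)]              # deletion of one color
        shift <- shift - 1L
      } else {
        cols <- append(cols, sample(0:3, 1), after = pos)  # insertion
        shift <- shift + 1L
      }
    }
    cols <- cols[seq_len(m)]
    # reading errors: position-dependent rate
    err_at <- which(stats::runif(m) < err_p)
    for (l in err_at) cols[l] <- (cols[l] + sample(1:3, 1)) %% 4L
    q <- qbase + a * stats::rnorm(5)[phase + 1L] + b * stats::rnorm(m)
    reads[[r]] <- new_color_read(cols, .code_base[codes[t0 + 1L] + 1L],
                                 pmax(1L, as.integer(round(q))))
    n_snp[r] <- length(snp_at); n_indel[r] <- length(ind_at)
    n_err[r] <- length(err_at)
  }
  tibble::tibble(id = sprintf("read_%d", seq_len(n_reads)), locus = loci,
                 read = reads, n_snp = n_snp, n_indel = n_indel, n_err = n_err)
}

#' Read a csfasta file (with optional QUAL file)
#'
#' csfasta records are a '>' header line followed by the primer base and the
#' color digits; QUAL files pair each header with space-separated integer
#' qualities.
#'
#' @param csfasta Path to the csfasta file.
#' @param qual Optional path to the matching QUAL file.
#' @return Tibble with columns `id` and `read` (list of `color_read`).
#' @export
read_csfasta <- function(csfasta, qual = NULL) {
  lines <- readLines(csfasta)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  hdr <- startsWith(lines, ">")
  if (!any(hdr)) stop("no csfasta records found", call. = FALSE)
  ids <- sub("^>\\s*", "", lines[hdr])
  seqs <- lines[!hdr]
  if (length(seqs) != length(ids)) {
    stop("malformed csfasta: record/sequence count mismatch", call. = FALSE)
  }
  quals <- NULL
  if (!is.null(qual)) {
    qlines <- readLines(qual)
    qlines <- qlines[!startsWith(qlines, "#") & nzchar(qlines)]
    qvals <- qlines[!startsWith(qlines, ">")]
    if (length(qvals) != length(ids)) {
      stop("QUAL file does not match csfasta record count", call. = FALSE)
    }
    quals <- lapply(strsplit(trimws(qvals), "\\s+"), as.integer)
  }
  reads <- lapply(seq_along(seqs), function(i) {
    s <- seqs[i]
    primer <- substr(s, 1, 1)
    digits <- strsplit(substr(s, 2, nchar(s)), "")[[1]]
    if (!all(digits %in% c("0", "1", "2", "3"))) {
      stop(sprintf("invalid color digits in record '%s'", ids[i]), call. = FALSE)
    }
    new_color_read(as.integer(digits), primer,
                   if (is.null(quals)) NULL else quals[[i]])
  })
  tibble::tibble(id = ids, read = reads)
}

#' Write color reads to csfasta (and optionally QUAL)
#'
#' @param reads Tibble as returned by [simulate_reads()] or [read_csfasta()],
#'   or a list of `color_read`s.
#' @param csfasta Output csfasta path.
#' @param qual Optional output QUAL path (requires qualities on every read).
#' @return Invisibly, the csfasta path.
#' @export
write_csfasta <- function(reads, csfasta, qual = NULL) {
  if (is.data.frame(reads)) {
    ids <- reads$id
    rs <- reads$read
  } else {
    rs <- reads
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("read_%d", seq_along(rs))
  }
  lines <- character(2L * length(rs))
  lines[c(TRUE, FALSE)] <- paste0(">", ids)
  lines[c(FALSE, TRUE)] <- vapply(rs, function(r) {
    paste0(r$primer_base, paste(r$colors, collapse = ""))
  }, character(1))
  writeLines(lines, csfasta)
  if (!is.null(qual)) {
    qlines <- character(2L * length(rs))
    qlines[c(TRUE, FALSE)] <- paste0(">", ids)
    qlines[c(FALSE, TRUE)] <- vapply(rs, function(r) {
      if (is.null(r$qualities)) stop("read without qualities", call. = FALSE)
      paste(r$qualities, collapse = " ")
    }, character(1))
    writeLines(qlines, qual)
  }
  invisible(csfasta)
}

#' Plot the quality autocorrelation by lag
#'
#' Lags that are multiples of 5 are highlighted; SOLiD chemistry elevates
#' correlations there.
#'
#' @param qc Tibble from [quality_correlation()].
#' @return A ggplot object.
#' @export
plot_quality_correlation <- function(qc) {
  qc$period5 <- qc$lag %% 5 == 0
  ggplot2::ggplot(qc, ggplot2::aes(x = .data$lag, y = .data$c,
                                   fill = .data$period5)) +
    ggplot2::geom_col(show.legend = TRUE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey55", `TRUE` = "firebrick"),
                               name = "lag %% 5 == 0") +
    ggplot2::labs(x = "lag (positions)", y = "quality correlation c(lag)") +
    ggplot2::theme_minimal()
}

#' Plot an empirical per-position error-rate profile
#'
#' @param rates Numeric vector of per-position mismatch rates.
#' @return A ggplot object.
#' @export
plot_error_profile <- function(rates) {
  df <- tibble::tibble(position = seq_along(rates) - 1L, rate = rates)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$rate)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "read position (colors, 0-based)",
                  y = "reading-error rate") +
    ggplot2::theme_minimal()
}
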