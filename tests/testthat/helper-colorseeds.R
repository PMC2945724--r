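# sample() that copes with length-1 vectors and caps at the population size
rsample <- function(v, n) {
  if (length(v) == 1) return(rep(v, min(n, 1)))
  sample(v, min(n, length(v)))
}

random_pattern <- function(w, s) {
  chars <- rep("#", s)
  if (s - w > 0) chars[rsample(2:(s - 1), s - w)] <- "-"
  parse_seed(paste(chars, collapse = ""))
}

random_family <- function(m, n_members = 1, w_range = 3:6, max_span = 9,
                          max_pos = 3) {
  members <- lapply(seq_len(n_members), function(i) {
    w <- sample(w_range, 1)
    s <- sample(w:min(max_span, m), 1)
    seed <- random_pattern(w, s)
    P <- sort(rsample(0:(m - seed$s), sample(1:max_pos, 1)))
    positioned_seed(seed, P, m)
  })
  seed_family(members, m)
}

reference_colors <- function(reference) {
  codes <- match(strsplit(reference, "")[[1]], c("A", "C", "G", "T")) - 1L
  bitwXor(codes[-length(codes)], codes[-1])
}
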