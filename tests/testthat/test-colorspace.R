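test_that("encode/decode round trip is the identity on nucleotide strings", {
  expect_equal(decode_from_colors(encode_to_colors("GATTACA", "T")), "GATTACA")
  expect_equal(encode_to_colors("A", "A")$colors, 0L)
  expect_equal(decode_from_colors(new_color_read(integer(0), "T")), "")
  set.seed(101)
  for (i in 1:50) {
    n <- sample(1:40, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    p <- sample(c("A", "C", "G", "T"), 1)
    expect_equal(decode_from_colors(encode_to_colors(s, p)), s)
  }
})

test_that("a single base substitution changes exactly two adjacent colors", {
  set.seed(102)
  for (i in 1:40) {
    n <- 10
    bases <- sample(c("A", "C", "G", "T"), n, TRUE)
    pos <- sample(2:(n - 1), 1)      # internal position
    alt <- sample(setdiff(c("A", "C", "G", "T"), bases[pos]), 1)
    mutated <- replace(bases, pos, alt)
    c1 <- encode_to_colors(bases, "T")$colors
    c2 <- encode_to_colors(mutated, "T")$colors
    changed <- which(c1 != c2)
    expect_length(changed, 2)
    expect_equal(diff(changed), 1)
    expect_equal(changed, c(pos, pos + 1))
  }
  # last-base substitution changes one color
  c1 <- encode_to_colors("ACGTA", "T")$colors
  c2 <- encode_to_colors("ACGTC", "T")$colors
  expect_length(which(c1 != c2), 1)
})

test_that("n consecutive substitutions affect at most n+1 consecutive colors", {
  set.seed(103)
  for (i in 1:30) {
    m <- 15
    bases <- sample(c("A", "C", "G", "T"), m, TRUE)
    n_mut <- sample(1:4, 1)
    start <- sample(2:(m - n_mut), 1)
    mutated <- bases
    for (j in start:(start + n_mut - 1)) {
      mutated[j] <- sample(setdiff(c("A", "C", "G", "T"), bases[j]), 1)
    }
    d <- which(encode_to_colors(bases, "T")$colors !=
                 encode_to_colors(mutated, "T")$colors)
    expect_lte(length(d), n_mut + 1)
    expect_lte(max(d) - min(d) + 1, n_mut + 1)
  }
})

test_that("a flipped color corrupts the whole decoded suffix", {
  r <- encode_to_colors("GATTACAGATT", "T")
  l <- 4
  r$colors[l] <- (r$colors[l] + 1L) %% 4L
  dec <- strsplit(decode_from_colors(r), "")[[1]]
  orig <- strsplit("GATTACAGATT", "")[[1]]
  expect_true(all(dec[seq_len(l - 1)] == orig[seq_len(l - 1)]))
  expect_true(all(dec[l:length(orig)] != orig[l:length(orig)]))
})

test_that("non-ACGT input is rejected with the offending position", {
  expect_error(encode_to_colors("ACNGT", "T"), "position 3")
  expect_error(new_color_read(c(0, 5), "T"), "0\\.\\.3")
})

test_that("quality_to_error_prob inverts the Phred transform", {
  expect_equal(quality_to_error_prob(0), 1.0)
  expect_equal(quality_to_error_prob(10), 0.1)
  expect_equal(quality_to_error_prob(20), 0.01)
  expect_error(quality_to_error_prob(-1), "non-negative")
})

test_that("quality correlation: constant qualities rejected, period 5 exact", {
  expect_error(quality_correlation(matrix(7, 10, 8)), "variance")
  Qp <- matrix(rep(rep(c(10, 20, 30, 15, 25), 4), 60), 60, 20, byrow = TRUE)
  qc <- quality_correlation(Qp, c(4, 5, 6))
  expect_equal(qc$c[qc$lag == 5], 1, tolerance = 1e-9)
  expect_lt(abs(qc$c[qc$lag == 4]), 1)
})

test_that("white-noise qualities stay within the 3/sqrt(N) envelope", {
  set.seed(104)
  n <- 2000; m <- 20
  Q <- matrix(round(rnorm(n * m, 25, 5)), n, m)
  qc <- quality_correlation(Q)
  N <- n * m
  expect_true(all(abs(qc$c) < 3 / sqrt(N) + 0.01))
  expect_true(all(abs(qc$c) <= 1 + 1e-9))
})

test_that("injected lag-5 correlation is recovered and peaks at multiples of 5", {
  Q <- simulate_quality_matrix(20000, 34, rho = 0.6, rng_seed = 5)
  qc <- quality_correlation(Q, 1:12)
  c5 <- qc$c[qc$lag == 5]
  expect_lt(abs(c5 - 0.6), 0.02)
  expect_gt(c5, qc$c[qc$lag == 4])
  expect_gt(c5, qc$c[qc$lag == 6])
  expect_gt(qc$c[qc$lag == 10], qc$c[qc$lag == 9])
})

test_that("error-free simulation reproduces reference colors at the locus", {
  set.seed(105)
  ref <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  p0 <- default_read_params()
  p0$p_snp <- 0; p0$p_indel <- 0
  p0$err_start <- 0; p0$err_end <- 0; p0$p_err_periodic <- 0
  reads <- simulate_reads(ref, 30, 20, p0, rng_seed = 3)
  refcols <- reference_colors(ref)
  for (i in seq_len(nrow(reads))) {
    expect_equal(reads$read[[i]]$colors,
                 refcols[(reads$locus[i] + 1):(reads$locus[i] + 20)])
  }
})

test_that("SNP-only simulation changes colors in adjacent XOR pairs", {
  set.seed(106)
  ref <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  p <- default_read_params()
  p$p_snp <- 0.2; p$p_indel <- 0
  p$err_start <- 0; p$err_end <- 0; p$p_err_periodic <- 0
  reads <- simulate_reads(ref, 60, 12, p, rng_seed = 8)
  refbases <- strsplit(ref, "")[[1]]
  for (i in seq_len(nrow(reads))) {
    # each SNP is a pair of adjacent color XORs, i.e. exactly one substituted
    # base: the decoded read differs from the reference substring at exactly
    # n_snp base positions
    t0 <- reads$locus[i]
    dec <- strsplit(decode_from_colors(reads$read[[i]]), "")[[1]]
    refseg <- refbases[(t0 + 2):(t0 + 13)]
    expect_equal(sum(dec != refseg), reads$n_snp[i])
  }
})

test_that("simulation is deterministic given the seed and m is enforced", {
  ref <- paste(rep("ACGTTGCA", 40), collapse = "")
  r1 <- simulate_reads(ref, 5, 20, rng_seed = 42)
  r2 <- simulate_reads(ref, 5, 20, rng_seed = 42)
  expect_identical(r1$read, r2$read)
  expect_identical(r1$locus, r2$locus)
  expect_error(simulate_reads("ACGTACGT", 2, 30, rng_seed = 1), "too short")
})

test_that("csfasta + QUAL round trip preserves reads", {
  ref <- paste(rep("ACGTTGCA", 40), collapse = "")
  reads <- simulate_reads(ref, 6, 15, rng_seed = 7)
  fc <- withr::local_tempfile(fileext = ".csfasta")
  fq <- withr::local_tempfile(fileext = ".qual")
  write_csfasta(reads, fc, fq)
  back <- read_csfasta(fc, fq)
  expect_equal(nrow(back), 6)
  for (i in 1:6) {
    expect_identical(back$read[[i]]$colors, reads$read[[i]]$colors)
    expect_identical(back$read[[i]]$qualities, reads$read[[i]]$qualities)
    expect_identical(back$read[[i]]$primer_base, reads$read[[i]]$primer_base)
  }
})

test_that("quality-correlation and error-profile plots build", {
  Q <- simulate_quality_matrix(200, 20, rng_seed = 2)
  p1 <- plot_quality_correlation(quality_correlation(Q))
  p2 <- plot_error_profile(read_error_profile(34))
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
})
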