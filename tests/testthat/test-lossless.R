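test_that("cost fold matches the printed event costs", {
  expect_equal(alignment_cost("110011"), 3)    # one SNP
  expect_equal(alignment_cost("1I11"), 4)      # one indel, no mismatch
  expect_equal(alignment_cost("10I011"), 6)    # mismatch + indel + free
  expect_equal(alignment_cost("01"), 2)        # leading mismatch: full cost
  expect_equal(alignment_cost(strrep("1", 8)), 0)
  # the four certified error combinations peak at total cost 7
  costs <- c(alignment_cost("1I10011"),      # 1 indel + 1 SNP      = 4 + 3
             alignment_cost("1I1101"),       # 1 indel + 1 error    = 4 + 2
             alignment_cost("10011001"),     # 2 SNPs               = 3 + 3
             alignment_cost("1001101011"))   # 1 SNP + 2 errors     = 3 + 4
  expect_equal(costs, c(7, 6, 6, 7))
  expect_equal(max(costs), 7)
})

test_that("the cost context automaton agrees with the fold everywhere", {
  ctx <- build_cost_automaton()
  run_cost <- function(sym) {
    q <- ctx$initial; tot <- 0
    for (s in sym) { tot <- tot + ctx$cost[q, s]; q <- ctx$delta[q, s] }
    tot
  }
  M <- colorseeds:::enumerate_strings(7, 3L)
  expect_identical(apply(M, 1, run_cost), apply(M, 1, alignment_cost))
})

test_that("SNP/error constraint automata accept exactly the decomposable strings", {
  a <- build_snp_error_automaton(1, 0)
  M <- colorseeds:::enumerate_strings(4, 2L)
  acc <- colorseeds:::dfa_accepts_matrix(a, M)
  lab <- apply(M, 1, function(r) paste(c("1", "0")[r], collapse = ""))
  expect_setequal(lab[acc], c("1111", "0011", "1001", "1100"))
  # k=0, h=0 accepts only the all-match string
  a0 <- build_snp_error_automaton(0, 0)
  expect_true(dfa_accepts(a0, "11111"))
  expect_false(dfa_accepts(a0, "11110"))
  # the 1-SNP-2-errors automaton, checked by enumeration
  a12 <- build_snp_error_automaton(1, 2)
  for (m in c(6, 9, 12)) {
    M <- colorseeds:::enumerate_strings(m, 2L)
    expect_identical(
      colorseeds:::dfa_accepts_matrix(a12, M),
      unname(apply(M, 1, function(r) colorseeds:::.event_feasible(r, 1, 2, 0))))
  }
  # with indels
  a111 <- build_error_budget_automaton(1, 1, 1)
  for (m in c(5, 7)) {
    M <- colorseeds:::enumerate_strings(m, 3L)
    expect_identical(
      colorseeds:::dfa_accepts_matrix(a111, M),
      unname(apply(M, 1, function(r) colorseeds:::.event_feasible(r, 1, 1, 1))))
  }
})

test_that("minimal-mismatch DP: textbook cases and witnesses", {
  # contiguous seed of span 3, all positions, m=5, one mismatch kills it
  fam <- seed_family("###", 5)
  v <- min_cost_dp(family_to_dfa(fam, "mm"), 5, 1, witness = TRUE)
  expect_false(v$lossless)
  expect_equal(v$min_missed_cost, 1)
  expect_equal(v$witness, "11011")
  expect_false(family_hits(fam, v$witness))
  # any feasible family is lossless for zero mismatches
  expect_true(min_cost_dp(family_to_dfa(fam, "mm"), 5, 0)$lossless)
  # a span-m seed at its single position dies to any single mismatch
  f2 <- seed_family(list(positioned_seed("#####", 0, 5)), 5)
  expect_false(min_cost_dp(family_to_dfa(f2, "mm"), 5, 1)$lossless)
})

test_that("DP verdict equals brute force on random instances (events)", {
  set.seed(601)
  for (i in 1:50) {
    m <- sample(10:20, 1)
    fam <- random_family(m, sample(1:2, 1), w_range = 6:10, max_span = 14,
                         max_pos = 4)
    b <- event_budget(sample(0:1, 1), sample(0:2, 1))
    v1 <- check_lossless(fam, b, m, witness = TRUE)
    v2 <- brute_force_lossless(fam, b, m)
    expect_identical(v1$lossless, v2$lossless)
    expect_equal(v1$min_missed_cost, v2$min_missed_cost)
    if (!v1$lossless) expect_false(family_hits(fam, v1$witness))
  }
})

test_that("DP verdict equals brute force with indels and cost budgets", {
  set.seed(602)
  for (i in 1:14) {
    m <- sample(8:12, 1)
    fam <- random_family(m, 1, w_range = 3:5, max_span = 7, max_pos = 3)
    b <- if (i %% 2) event_budget(sample(0:1, 1), sample(0:1, 1), 1) else
      cost_budget(sample(4:6, 1))
    v1 <- check_lossless(fam, b, m, witness = TRUE)
    v2 <- brute_force_lossless(fam, b, m)
    expect_identical(v1$lossless, v2$lossless)
    if (!v1$lossless) {
      expect_false(family_hits(fam, v1$witness))
      if (b$type == "cost") {
        expect_lte(alignment_cost(v1$witness), b$threshold)
      }
    }
  }
})

test_that("losslessness is monotone in threshold and in positions", {
  set.seed(603)
  for (i in 1:10) {
    m <- sample(12:18, 1)
    fam <- random_family(m, 1, w_range = 4:6, max_span = 9, max_pos = 3)
    fd <- family_to_dfa(fam, "mm")
    fd$cost <- matrix(rep(c(0, 1), each = nrow(fd$delta)), ncol = 2)
    ks <- 0:3
    verdicts <- vapply(ks, function(k) min_cost_dp(fd, m, k)$lossless,
                       logical(1))
    # lossless at t implies lossless at every smaller threshold
    expect_true(all(diff(rev(verdicts)) >= 0) || all(!verdicts) ||
                  all(cummin(verdicts) == verdicts))
    # enlarging a position set preserves losslessness
    mem <- fam$members[[1]]
    valid <- 0:(m - mem$seed$s)
    extra <- setdiff(valid, mem$positions)
    if (length(extra)) {
      fam2 <- seed_family(list(positioned_seed(mem$seed,
                                               sort(c(mem$positions,
                                                      extra[1])), m)), m)
      for (k in ks) {
        if (check_lossless(fam, mismatch_budget(k), m)$lossless) {
          expect_true(check_lossless(fam2, mismatch_budget(k), m)$lossless)
        }
      }
    }
  }
})

test_that("a positioned family lossless at m stays lossless at larger m", {
  set.seed(604)
  found <- 0
  for (i in 1:40) {
    m <- sample(10:16, 1)
    fam <- random_family(m, 2, w_range = 2:4, max_span = 5, max_pos = 4)
    b <- event_budget(1, 0)
    if (!check_lossless(fam, b, m)$lossless) next
    found <- found + 1
    for (mp in (m + 1):(m + 4)) {
      famp <- seed_family(lapply(fam$members, function(x) {
        positioned_seed(x$seed, x$positions, mp)
      }), mp)
      expect_true(check_lossless(famp, b, mp)$lossless)
    }
    if (found >= 5) break
  }
  expect_gte(found, 1)
})

test_that("nonconsecutive-SNP losslessness covers consecutive SNPs", {
  # k consecutive SNPs appear as a run of k+1 adjacent color mismatches;
  # a family lossless for k nonconsecutive SNPs must hit those too
  set.seed(605)
  k <- 2
  checked <- 0
  for (i in 1:40) {
    m <- sample(10:14, 1)
    fam <- random_family(m, 2, w_range = 2:3, max_span = 4, max_pos = 4)
    if (!check_lossless(fam, event_budget(k, 0), m)$lossless) next
    checked <- checked + 1
    for (start in 1:(m - k)) {
      syms <- rep(1L, m)
      syms[start:(start + k)] <- 2L     # run of k+1 mismatches
      expect_true(family_hits(fam, syms))
    }
    if (checked >= 3) break
  }
  expect_gte(checked, 1)
})

test_that("budget-0 brute force reduces to the all-match string", {
  fam <- seed_family(list(positioned_seed("##", 1, 4)), 4)
  v <- brute_force_lossless(fam, mismatch_budget(0), 4)
  expect_true(v$lossless)
  f0 <- seed_family(list(positioned_seed("###", integer(0), 4)), 4)
  expect_false(brute_force_lossless(f0, mismatch_budget(0), 4)$lossless)
  expect_error(brute_force_lossless(fam, mismatch_budget(3), 40, guard = 100),
               "guard")
})
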