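test_that("seed automaton accepts exactly the strings containing a hit", {
  d <- seed_to_dfa("###")
  expect_lte(n_states(d), 4)
  expect_true(dfa_accepts(d, "111"))
  expect_true(dfa_accepts(d, "0111"))
  expect_false(dfa_accepts(d, "11011"))
  d2 <- seed_to_dfa("#-#")
  expect_true(dfa_accepts(d2, "101"))
  expect_true(dfa_accepts(d2, "111"))
  expect_false(dfa_accepts(d2, "100"))
  expect_false(dfa_accepts(d2, "001"))
  expect_true(finals_absorbing(d2))
  # random seeds: language equals the brute-force hit scan
  set.seed(301)
  for (i in 1:25) {
    seed <- random_pattern(sample(2:5, 1), sample(3:8, 1))
    d <- seed_to_dfa(seed)
    m <- seed$s + sample(1:3, 1)
    M <- colorseeds:::enumerate_strings(m, 2L)
    acc <- colorseeds:::dfa_accepts_matrix(d, M)
    oracle <- apply(M, 1, function(al) {
      any(vapply(0:(m - seed$s), function(p) seed_hits(seed, al, p),
                 logical(1)))
    })
    expect_identical(acc, unname(oracle))
  }
})

test_that("seed automaton size respects the (w+1)*2^(s-w) bound", {
  set.seed(302)
  for (i in 1:40) {
    w <- sample(3:8, 1)
    gap <- sample(0:6, 1)
    s <- w + gap
    if (gap > max(s - 2, 0)) next
    seed <- random_pattern(w, s)
    expect_lte(n_states(seed_to_dfa(seed)), (w + 1) * 2^(s - w))
  }
  expect_lte(n_states(seed_to_dfa("####-##-####")), 44)  # w=10, s=12
})

test_that("position chain finality follows i - s in P", {
  ch <- position_chain(4, 2, 0)
  expect_equal(which(ch$finals) - 1L, 2L)      # q_2 final
  ch2 <- position_chain(4, 2, c(0, 1, 2))
  expect_equal(which(ch2$finals) - 1L, c(2L, 3L, 4L))
  expect_error(position_chain(4, 5, 0), "p \\+ s <= m")
  expect_warning(position_chain(4, 2, integer(0)), "no final state")
})

test_that("seed x chain product restricts hits to allowed start positions", {
  # seed "##", m=3, P={1}: occurrence must start at read position 1
  pr <- dfa_product(seed_to_dfa("##", "suffix"), position_chain(3, 2, 1),
                    "AND", absorb = TRUE)
  expect_true(dfa_accepts(pr, "011"))
  expect_true(dfa_accepts(pr, "111"))
  expect_false(dfa_accepts(pr, "110"))
  M <- colorseeds:::enumerate_strings(3, 2L)
  fam <- seed_family(list(positioned_seed("##", 1, 3)), 3)
  expect_identical(colorseeds:::dfa_accepts_matrix(pr, M),
                   colorseeds:::family_hits_matrix(fam, M))
  expect_error(dfa_product(seed_to_dfa("##"), position_chain(3, 2, 1, "mmi")),
               "modes differ")
})

test_that("product with all positions is language-equivalent to the seed DFA", {
  set.seed(303)
  for (i in 1:10) {
    seed <- random_pattern(sample(2:4, 1), sample(3:6, 1))
    m <- sample(seed$s:10, 1)
    full <- dfa_product(seed_to_dfa(seed, "suffix"),
                        position_chain(m, seed$s, 0:(m - seed$s)),
                        "AND", absorb = TRUE)
    plain <- seed_to_dfa(seed)
    M <- colorseeds:::enumerate_strings(m, 2L)
    expect_identical(colorseeds:::dfa_accepts_matrix(full, M),
                     colorseeds:::dfa_accepts_matrix(plain, M))
  }
})

test_that("position product size respects the compact product bound", {
  set.seed(304)
  for (i in 1:25) {
    seed <- random_pattern(sample(3:7, 1), sample(4:10, 1))
    m <- seed$s + sample(2:10, 1)
    P <- sort(rsample(0:(m - seed$s), sample(1:4, 1)))
    pr <- minimize_dfa(dfa_product(seed_to_dfa(seed, "suffix"),
                                   position_chain(m, seed$s, P),
                                   "AND", absorb = TRUE))
    bound <- (seed$w + 1) * 2^(seed$s - seed$w) * length(P) + m
    expect_lte(n_states(pr), bound)
  }
})

test_that("family automaton equals the brute-force placement scan", {
  set.seed(305)
  for (i in 1:25) {
    m <- sample(5:9, 1)
    fam <- random_family(m, sample(1:2, 1), w_range = 2:4, max_span = 6)
    fd <- family_to_dfa(fam, "mm")
    expect_true(finals_absorbing(fd))
    M <- colorseeds:::enumerate_strings(m, 2L)
    expect_identical(colorseeds:::dfa_accepts_matrix(fd, M),
                     colorseeds:::family_hits_matrix(fam, M))
    # 3-symbol mode against the read-coordinate scan
    fd3 <- family_to_dfa(fam, "mmi")
    M3 <- colorseeds:::enumerate_strings(min(m, 7), 3L)
    if (ncol(M3) == m) {
      expect_identical(colorseeds:::dfa_accepts_matrix(fd3, M3),
                       colorseeds:::family_hits_matrix(fam, M3))
    }
  }
  # single-member family == product construction
  fam <- seed_family(list(positioned_seed("##-#", c(1, 3), 8)), 8)
  fd <- family_to_dfa(fam, "mm")
  pr <- dfa_product(seed_to_dfa("##-#", "suffix"), position_chain(8, 4, c(1, 3)),
                    "AND", absorb = TRUE)
  M <- colorseeds:::enumerate_strings(8, 2L)
  expect_identical(colorseeds:::dfa_accepts_matrix(fd, M),
                   colorseeds:::dfa_accepts_matrix(pr, M))
  # two disjoint-position copies accept the union of the single languages
  f1 <- seed_family(list(positioned_seed("##", 0, 6)), 6)
  f2 <- seed_family(list(positioned_seed("##", 4, 6)), 6)
  f12 <- seed_family(list(positioned_seed("##", 0, 6),
                          positioned_seed("##", 4, 6)), 6)
  M <- colorseeds:::enumerate_strings(6, 2L)
  expect_identical(
    colorseeds:::dfa_accepts_matrix(family_to_dfa(f12), M),
    colorseeds:::dfa_accepts_matrix(family_to_dfa(f1), M) |
      colorseeds:::dfa_accepts_matrix(family_to_dfa(f2), M))
})

test_that("indel symbols reset partial matches but spare later windows", {
  he <- indel_extend(seed_to_dfa("##"))
  expect_equal(he$mode, "mmi")
  expect_true(dfa_accepts(he, "1I11"))   # window after the indel
  expect_false(dfa_accepts(he, "1I1"))
  # indel-free strings: conservative extension
  d <- seed_to_dfa("#-##")
  de <- indel_extend(d)
  M <- colorseeds:::enumerate_strings(6, 2L)
  expect_identical(colorseeds:::dfa_accepts_matrix(de, M),
                   colorseeds:::dfa_accepts_matrix(d, M))
  # family route agrees
  fam <- seed_family(list(positioned_seed("##", "*", 4)), 4)
  fe <- indel_extend(family_to_dfa(fam, "mm"))
  expect_true(dfa_accepts(fe, "1I11"))
  expect_false(dfa_accepts(fe, "1I1I"))
})

test_that("constructed hit automata have absorbing finals", {
  set.seed(306)
  for (i in 1:10) {
    fam <- random_family(sample(6:12, 1), sample(1:2, 1))
    expect_true(finals_absorbing(family_to_dfa(fam, "mm")))
    expect_true(finals_absorbing(family_to_dfa(fam, "mmi")))
    expect_true(finals_absorbing(seed_to_dfa(random_pattern(3, 5))))
  }
})

test_that("automaton dump/load round trips the transition table", {
  fam <- seed_family(list(positioned_seed("#-#", c(0, 2), 6)), 6)
  d <- family_to_dfa(fam, "mm")
  f <- withr::local_tempfile(fileext = ".dfa")
  dfa_write(d, f)
  back <- dfa_read(f)
  expect_equal(back$mode, d$mode)
  M <- colorseeds:::enumerate_strings(6, 2L)
  expect_identical(colorseeds:::dfa_accepts_matrix(back, M),
                   colorseeds:::dfa_accepts_matrix(d, M))
  # weighted automaton keeps costs
  ctx <- build_cost_automaton()
  f2 <- withr::local_tempfile(fileext = ".dfa")
  dfa_write(ctx, f2)
  back2 <- dfa_read(f2)
  expect_equal(back2$cost, ctx$cost)
})
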