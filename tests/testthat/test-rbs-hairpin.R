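test_that("rbs_score matches exhaustive placement enumeration", {
  model <- rbs_model()
  # perfect consensus at a valid spacer
  w <- paste0(random_seq(6), "AGGAGG", strrep("C", 6))
  expect_equal(rbs_score(w, model)$score, 6L)
  # featureless window
  expect_equal(rbs_score(strrep("C", 25), model)$score, 0L)
  set.seed(600)
  for (i in 1:200) {
    win <- random_seq(sample(3:30, 1), gc = runif(1, 0.3, 0.7))
    got <- rbs_score(win, model)
    expect_equal(got$score, oracle_rbs_score(win, model), info = win)
  }
  # deterministic tie-break: smallest spacer among equal scores
  tie <- strrep("A", 26)  # every placement scores the same (A vs AGGAGG)
  expect_equal(rbs_score(tie, model)$spacer, model$spacer_min)
})

test_that("silent_rbs_boost is optimal over all silent variants", {
  model <- rbs_model()
  set.seed(601)
  n_checked <- 0L
  while (n_checked < 15L) {
    nc <- sample(3:8, 1)
    tail <- random_cds_fragment(nc)
    variants <- oracle_silent_variants(tail, test_table)
    if (length(variants) > 25000L) next
    n_checked <- n_checked + 1L
    b <- silent_rbs_boost(tail, test_table, model)
    best <- max(vapply(variants, oracle_rbs_score, 0L, model = model))
    expect_equal(b$score_after, best, info = tail)
    expect_gte(b$score_after, b$score_before)
    expect_equal(translate_cds(b$modified_tail), translate_cds(tail))
  }
})

test_that("silent_rbs_boost leaves optimal or rigid tails unchanged", {
  model <- rbs_model()
  # already containing the consensus at a valid spacer: AGG AGG are Arg
  # codons, so the consensus itself is silent-reachable and maximal
  tail <- paste0("AGGAGG", "GCTGCA", "GCC")  # consensus at spacer 9
  b <- silent_rbs_boost(tail, test_table, model)
  expect_equal(b$score_after, 6L)
  # Met/Trp-only tail: no silent degrees of freedom
  rigid <- strrep("ATGTGG", 3)
  b2 <- silent_rbs_boost(rigid, test_table, model)
  expect_equal(b2$modified_tail, rigid)
  expect_equal(nrow(b2$mutations), 0L)
  expect_equal(b2$score_after, b2$score_before)
})

test_that("hairpin_screen finds planted stems and nothing in poly-A", {
  set.seed(602)
  s <- random_seq(10, gc = 0.6)
  seq1 <- paste0(s, "TTTT", revcomp(s))
  hits <- hairpin_screen(seq1, min_stem = 8, loop_min = 3, loop_max = 6)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$stem_len, 10L)
  expect_equal(hits$pos5, 1L)
  expect_equal(hits$loop_len, 4L)
  expect_equal(nrow(hairpin_screen(strrep("A", 50), 3, 3, 10)), 0L)
  expect_error(hairpin_screen("ACGT", min_stem = 2), "min_stem")
})

test_that("hairpin_screen agrees with the complement-matrix oracle", {
  set.seed(603)
  for (i in 1:8) {
    seq <- if (i <= 4) {
      # plant a hairpin into a random background
      s <- random_seq(sample(6:12, 1), gc = 0.7)
      paste0(random_seq(40), s, random_seq(sample(3:8, 1)), revcomp(s),
             random_seq(40))
    } else {
      random_seq(200, gc = runif(1, 0.4, 0.6))
    }
    ms <- sample(4:8, 1)
    expect_equal(hairpin_screen(seq, ms, 3, 10),
                 oracle_hairpins(seq, ms, 3, 10), info = seq)
  }
})
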