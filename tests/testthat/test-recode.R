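test_that("single-codon families pass through and are flagged unchangeable", {
  r <- recode_synonymous("ATG", test_table)
  expect_equal(r$recoded, "ATG")
  expect_false(r$report$changed)
  expect_false(r$report$degenerate)
  r2 <- recode_synonymous("TGG", test_table)
  expect_equal(r2$recoded, "TGG")
})

test_that("serine AGC recodes to a maximally distant synonym", {
  # the Hamming-3 synonyms of AGC are {TCA, TCG, TCT} - the set that
  # contains the published AGC<->TCT serine swap; lexicographic tie-break
  # picks TCA, the E. coli usage tie-break picks TCG
  max_set <- c("TCA", "TCG", "TCT")
  plain <- recode_synonymous("AGC", test_table)
  expect_equal(plain$recoded, "TCA")
  usage <- recode_synonymous(
    "AGC", test_table, recode_options(codon_usage = ecoli_codon_usage()))
  expect_equal(usage$recoded, "TCG")
  for (r in list(plain, usage)) {
    expect_true(r$recoded %in% max_set)
    expect_equal(translate_cds(r$recoded), "S")
    expect_true(r$report$changed)
  }
  # the published choice TCT is itself an accepted maximal output
  expect_equal(translate_cds("TCT"), translate_cds("AGC"))
  expect_true("TCT" %in% max_set)
})

test_that("recoding matches exhaustive enumeration on short fragments", {
  set.seed(500)
  opts_plain <- recode_options(w_max = 30L)
  opts_usage <- recode_options(w_max = 30L, codon_usage = ecoli_codon_usage())
  heavy <- c("CTG", "AGC", "CGT", "TCC", "TTA", "CGG")  # Leu/Ser/Arg pool
  for (i in 1:20) {
    n <- sample(2:6, 1)
    frag <- if (i <= 10) {
      paste(sample(heavy, n, replace = TRUE), collapse = "")
    } else {
      random_cds_fragment(n)
    }
    expect_equal(recode_synonymous(frag, test_table, opts_plain)$recoded,
                 oracle_recode(frag, test_table), info = frag)
    expect_equal(recode_synonymous(frag, test_table, opts_usage)$recoded,
                 oracle_recode(frag, test_table, ecoli_codon_usage()),
                 info = frag)
  }
})

test_that("recoding preserves the protein and changes every degenerate codon", {
  set.seed(501)
  for (i in 1:50) {
    frag <- random_cds_fragment(sample(5:40, 1))
    r <- recode_synonymous(frag, test_table)
    expect_equal(translate_cds(r$recoded), translate_cds(frag))
    expect_true(all(r$report$changed[r$report$degenerate]))
    expect_lte(max_shared_window(r$recoded, frag), recode_options()$w_max)
    # idempotent in protein space under repeated recoding
    r2 <- recode_synonymous(r$recoded, test_table)
    expect_equal(translate_cds(r2$recoded), translate_cds(frag))
  }
})

test_that("forbidden motifs are repaired away or reported infeasible", {
  site <- iscei_site(test_library)
  set.seed(502)
  for (i in 1:20) {
    frag <- random_cds_fragment(sample(8:25, 1))
    r <- recode_synonymous(frag, test_table,
                           recode_options(forbidden_motifs = site))
    expect_equal(nrow(scan_motif(r$recoded, site, both_strands = TRUE)), 0L)
    expect_equal(translate_cds(r$recoded), translate_cds(frag))
  }
})

test_that("an unchangeable run longer than w_max is reported infeasible", {
  frag <- strrep("ATGTGG", 5)  # Met/Trp alternation, 30 bp, no synonyms
  expect_error(recode_synonymous(frag, test_table, recode_options(w_max = 14L)),
               "infeasible")
})

test_that("internal stops and frame violations are rejected", {
  expect_error(recode_synonymous("ATGTAAAAA", test_table), "internal stop")
  expect_error(recode_synonymous("ATGA", test_table), "divisible")
  # a terminal stop codon is allowed and recoded synonymously
  r <- recode_synonymous("ATGTAA", test_table)
  expect_equal(translate_cds(r$recoded), "M*")
  expect_true(r$report$changed[2])
})

test_that("max_shared_window agrees with the diagonal-scan oracle", {
  a30 <- random_seq(30)
  expect_equal(max_shared_window(a30, a30), 30L)
  expect_equal(max_shared_window("AAAA", "TTTT"), 0L)
  expect_equal(max_shared_window("", "ACGT"), 0L)
  set.seed(503)
  for (i in 1:25) {
    a <- random_seq(sample(20:500, 1), gc = runif(1, 0.3, 0.7))
    b <- if (i %% 3 == 0) {
      # plant a shared block to exercise long windows
      k <- sample(5:15, 1)
      at <- sample(nchar(a) - k, 1)
      paste0(random_seq(50), substr(a, at, at + k - 1L), random_seq(50))
    } else {
      random_seq(sample(20:500, 1))
    }
    expect_equal(max_shared_window(a, b), oracle_lcs(a, b))
  }
})
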