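test_that("sequence normalization accepts ACGT/u and rejects ambiguity codes", {
  expect_equal(nuc("acgt"), "ACGT")
  expect_equal(nuc("augc"), "ATGC")
  expect_equal(nuc(""), "")
  expect_error(nuc("ACGN"), "non-ACGT")
  expect_error(nuc("ACG-T"), "non-ACGT")
})

test_that("translation follows the bacterial code and enforces frame", {
  expect_equal(translate_cds("ATGAGC"), "MS")
  expect_equal(translate_cds(""), "")
  expect_equal(translate_cds("AGC"), translate_cds("TCT"))
  expect_equal(translate_cds("AGC"), "S")
  expect_equal(translate_cds("TAA"), "*")
  expect_error(translate_cds("ATGA"), "frame")
  # bacterial alternative initiators render as M only when required
  expect_equal(translate_cds("GTGAAA"), "VK")
  expect_equal(translate_cds("GTGAAA", require_start = TRUE), "MK")
  expect_error(translate_cds("CCCAAA", require_start = TRUE), "initiation")
})

test_that("revcomp is an involution and handles palindromes", {
  expect_equal(revcomp("ACGT"), "ACGT")
  expect_equal(revcomp("AAA"), "TTT")
  set.seed(42)
  for (i in 1:25) {
    x <- random_seq(sample(1:80, 1))
    expect_equal(revcomp(revcomp(x)), x)
  }
})

test_that("translating a reverse-strand CDS equals the plus-strand revcomp path", {
  g <- mixed_genome(seed = 310L)
  minus <- g$features[g$features$strand == "-" & g$features$kind == "CDS", ]
  expect_gt(nrow(minus), 0L)
  f <- minus[1L, ]
  direct <- translate_cds(feature_seq(g, f$feature_id))
  via_plus <- translate_cds(revcomp(substr(g$contigs[[f$contig]],
                                           f$start, f$end)))
  expect_equal(direct, via_plus)
  expect_match(direct, "\\*$")
})

test_that("motif scanning reports overlapping hits and agrees with brute force", {
  expect_equal(scan_motif("AAAA", "AA")$pos, c(1L, 2L, 3L))
  expect_error(scan_motif("ACGT", ""), "non-empty")
  # constructed unique site
  site <- iscei_site(test_library)
  set.seed(7)
  repeat {
    x <- random_seq(500); y <- random_seq(400)
    if (nrow(scan_motif(paste0(x, y), site, TRUE)) == 0L) break
  }
  s <- paste0(x, site, y)
  hits <- scan_motif(s, site)
  expect_equal(hits$pos, nchar(x) + 1L)
  # randomized agreement with the sliding-window oracle
  set.seed(99)
  for (i in 1:300) {
    seq <- random_seq(sample(30:200, 1), gc = runif(1, 0.2, 0.8))
    motif <- random_seq(sample(2:6, 1))
    both <- i %% 2 == 0
    expect_identical(scan_motif(seq, motif, both),
                     oracle_scan(seq, motif, both))
  }
})

test_that("codon windows are the 3n-2..3n arithmetic and tile the CDS", {
  expect_equal(codon_window(1), cbind(start = 1L, end = 3L))
  w <- codon_window(1:50)
  expect_true(all(w[, "end"] - w[, "start"] == 2L))
  expect_equal(w[-1, "start"], w[-50, "end"] + 1L)  # no gaps, no overlaps
  expect_equal(unname(w[50, "end"]), 150L)
  expect_error(codon_window(0), "residue_index")
})
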