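test_that("eligible_segments returns maximal runs of pairing-capable bases", {
  expect_equal(eligible_segments(rep(TRUE, 100), 30),
               data.frame(start = 1L, end = 100L))
  expect_equal(nrow(eligible_segments(rep(FALSE, 40), 5)), 0L)
  set.seed(700)
  for (i in 1:100) {
    m <- runif(sample(10:150, 1)) < runif(1, 0.3, 0.9)
    w <- sample(1:10, 1)
    expect_equal(eligible_segments(m, w), oracle_eligible_segments(m, w))
  }
  expect_error(eligible_segments(rep(TRUE, 5), 0), "w must be")
})

test_that("p_desired_integration matches per-base crossover enumeration", {
  # symmetric geometry: equal eligible length on both sides of the edit
  m <- rep(TRUE, 61); m[31] <- FALSE
  expect_equal(p_desired_integration(m, 31, 5), 0.5)
  # recoded limit: the only eligible bases lie 3' of the mutation
  m2 <- c(rep(FALSE, 40), rep(TRUE, 30)); m2[40] <- FALSE
  expect_equal(p_desired_integration(m2, 40, 5), 1.0)
  # toy mask from the identity-breaking geometry
  m3 <- rep(TRUE, 60); m3[20:40] <- FALSE; m3[45] <- FALSE
  expect_equal(p_desired_integration(m3, 45, 5),
               oracle_p_desired(m3, 45, 5))
  set.seed(701)
  for (i in 1:300) {
    n <- sample(20:200, 1)
    m <- runif(n) < runif(1, 0.5, 0.98)
    mut <- sort(sample(n, sample(1:3, 1)))
    m[mut] <- FALSE
    w <- sample(2:30, 1)
    p_ok <- tryCatch(p_desired_integration(m, mut, w), error = function(e) NA)
    o_ok <- tryCatch(oracle_p_desired(m, mut, w), error = function(e) NA)
    expect_equal(p_ok, o_ok)
  }
})

test_that("p_desired_integration validates its inputs", {
  m <- rep(TRUE, 10); m[5] <- FALSE
  expect_error(p_desired_integration(m, integer(0), 3), "no mutation")
  expect_error(p_desired_integration(m, 4, 3), "FALSE at every mutation")
  expect_error(p_desired_integration(rep(FALSE, 10), 5, 3), "infeasible")
  expect_error(p_desired_integration(m, 20, 3), "outside")
})

test_that("extending the recoded region 5' of the mutation never lowers p", {
  set.seed(702)
  for (i in 1:30) {
    n <- 150L
    mut <- sample(60:120, 1)
    m <- rep(TRUE, n); m[mut] <- FALSE
    w <- sample(5:25, 1)
    last <- p_desired_integration(m, mut, w)
    # progressively destroy identity 5' of the mutation
    for (cut in seq(mut - 10L, 10L, by = -20L)) {
      m[seq_len(cut)] <- FALSE
      p <- tryCatch(p_desired_integration(m, mut, w), error = function(e) NA)
      if (is.na(p)) break
      expect_gte(p, last)
      last <- p
    }
  }
})

test_that("integration replaces the anchored span and errors on ambiguity", {
  g <- plus_genome(710L)
  set.seed(710)
  e <- random_edit(g, test_library, kind = "deletion")
  d <- design_cassette(e, g, test_library)
  inter <- integrate_in_silico(g, d$cassette)
  # length identity: genome - replaced span + cassette length
  hr1 <- scan_motif(g$contigs[["chr"]], cassette_part_seq(d$cassette, "HR1"))
  hr2 <- scan_motif(g$contigs[["chr"]], cassette_part_seq(d$cassette, "HR2"))
  replaced <- hr2$pos + 100L - hr1$pos
  expect_equal(nchar(inter$contigs[["chr"]]),
               nchar(g$contigs[["chr"]]) - replaced +
                 nchar(cassette_seq(d$cassette)))
  # intermediate carries marker, single I-SceI site, both HR3 copies,
  # and the terminators
  s <- inter$contigs[["chr"]]
  expect_equal(nrow(scan_motif(s, iscei_site(test_library), TRUE)), 1L)
  expect_equal(length(scan_motif(s, d$cassette$hr3)$pos), 2L)
  expect_equal(nrow(scan_motif(s, lib_part(test_library, "cat")$seq)), 1L)
  for (p in lib_part(test_library, role = "terminator")) {
    expect_gte(nrow(scan_motif(s, p$seq, both_strands = TRUE)), 1L)
  }
  # duplicated HR1 anchor -> targeting error
  g2 <- g
  g2$contigs[["chr"]] <- paste0(g$contigs[["chr"]],
                                cassette_part_seq(d$cassette, "HR1"))
  expect_error(integrate_in_silico(g2, d$cassette), "targeting")
})

test_that("cleave_and_resolve demands one site and two identical HR3 copies", {
  g <- plus_genome(711L)
  set.seed(711)
  e <- random_edit(g, test_library, kind = "point_mutation")
  d <- design_cassette(e, g, test_library)
  inter <- integrate_in_silico(g, d$cassette)
  # removing the I-SceI site by hand -> cleavage error
  broken <- inter
  broken$contigs[["chr"]] <- gsub(iscei_site(test_library), "",
                                  inter$contigs[["chr"]], fixed = TRUE)
  expect_error(cleave_and_resolve(broken, d$cassette, test_library),
               "cleavage error")
  # resolution yields exactly the intended edit
  final <- cleave_and_resolve(inter, d$cassette, test_library)
  expect_identical(final$contigs, apply_edit(g, e)$contigs)
  expect_false(contains_scar(final))
})

test_that("essential-gene intermediates carry a complete functional ORF", {
  g <- plus_genome(712L)
  f <- g$features[g$features$kind == "CDS", ][2L, ]
  wt_prot <- translate_cds(feature_seq(g, f$feature_id))
  cds <- feature_seq(g, f$feature_id)
  r <- 40L
  from <- substr(cds, 3L * r - 2L, 3L * r)
  to <- setdiff(syn_of(from), from)[1L]
  expect_false(is.na(to))
  for (variant in c("own_promoter", "wt_restoring")) {
    e <- edit_essential(f$feature_id, r, to, variant)
    d <- design_cassette(e, g, test_library)
    inter <- integrate_in_silico(g, d$cassette)
    # the reconstituted ORF begins at the original CDS start position
    s <- inter$contigs[["chr"]]
    orf <- substr(s, f$start, nchar(s))
    cods <- substring(orf, seq(1, nchar(orf) - 2, 3), seq(3, nchar(orf), 3))
    aa <- unname(test_table$code[cods])
    stop_at <- which(aa == "*")[1]
    prot <- paste(c(aa[seq_len(stop_at - 1)], "*"), collapse = "")
    if (variant == "wt_restoring") {
      expect_equal(prot, wt_prot)
    } else {
      edited_prot <- translate_cds(paste0(
        substr(cds, 1, 3L * r - 3L), to,
        substr(cds, 3L * r + 1L, nchar(cds))))
      expect_equal(prot, edited_prot)
    }
    final <- cleave_and_resolve(inter, d$cassette, test_library)
    expect_identical(final$contigs, apply_edit(g, e)$contigs)
  }
})
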