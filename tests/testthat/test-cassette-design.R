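test_that("HR3 windows center the edit with the documented tie-breaks", {
  g <- plus_genome(800L)
  G <- g$contigs[["chr"]]
  # single point mutation in a 40 bp window sits at offset 20 (1-based),
  # i.e. 19 bp of context 5' and 20 bp 3'
  pos <- 1000L
  old <- substr(G, pos, pos)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  hw <- choose_hr3(g, edit_point_mutation("chr", pos, new), design_config())
  expect_equal(nchar(hw$hr3), 40L)
  expect_equal(hw$h1, pos - 19L)
  expect_equal(hw$h2, pos + 20L)
  expect_equal(substr(hw$hr3, 20L, 20L), new)
  expect_equal(hw$placement, "inside_hr3")
  # deletion: fusion of the 20 bp before and the 20 bp after the span
  del <- edit_deletion("chr", 1200L, 1699L)
  hwd <- choose_hr3(g, del, design_config())
  expect_equal(hwd$hr3, paste0(substr(G, 1180L, 1199L),
                               substr(G, 1700L, 1719L)))
  # small insertion is embedded; a long one falls back to after_hr3
  small <- choose_hr3(g, edit_insertion("chr", 900L, "ACGTAC"),
                      design_config())
  expect_equal(small$placement, "inside_hr3")
  expect_true(grepl("ACGTAC", small$hr3, fixed = TRUE))
  big <- choose_hr3(g, edit_insertion("chr", 900L, random_seq(66)),
                    design_config())
  expect_equal(big$placement, "after_hr3")
  expect_equal(big$hr3, substr(G, 900L - 39L, 900L))
})

test_that("selection cassettes follow the published element order", {
  lib <- test_library
  sc0 <- build_selection_cassette("cat", 0, lib)
  labels0 <- vapply(sc0$segments, `[[`, "", "label")
  expect_equal(labels0, c("ISceI_site", "MARKER_cat"))
  expect_equal(sc0$segments[[1]]$seq, iscei_site(lib))
  sc2 <- build_selection_cassette("cat", 2, lib)
  labels2 <- vapply(sc2$segments, `[[`, "", "label")
  site_at <- which(labels2 == "ISceI_site")
  expect_equal(sum(grepl("^TERM", labels2)), 2L)
  expect_true(all(which(grepl("^TERM", labels2)) < site_at))
  expect_lt(site_at, which(labels2 == "MARKER_cat"))
  expect_error(build_selection_cassette("nope", 2, lib), "no part named")
  expect_error(build_selection_cassette("ISceI", 2, lib), "role 'marker'")
})

test_that("a boosted marker tail keeps the marker protein and raises the score", {
  lib <- test_library
  plain <- build_selection_cassette("cat", 2, lib)
  boosted <- build_selection_cassette("cat", 2, lib, rbs_boost_tail = TRUE)
  mseq <- function(sc) {
    sc$segments[[which(vapply(sc$segments, `[[`, "", "role") == "marker")]]$seq
  }
  expect_equal(translate_cds(mseq(boosted), lib$table),
               translate_cds(mseq(plain), lib$table))
  expect_gte(boosted$boost$score_after, boosted$boost$score_before)
  # the synthetic cat tail is improvable, so the boost bites
  expect_gt(boosted$boost$score_after, rbs_score(
    substr(mseq(plain), nchar(mseq(plain)) - 23L, nchar(mseq(plain))))$score)
})

test_that("cassette structure invariants hold across kinds and variants", {
  g <- mixed_genome(801L)
  lib <- test_library
  set.seed(801)
  cases <- list(
    random_edit(g, lib, "point_mutation"),
    random_edit(g, lib, "insertion"),
    random_edit(g, lib, "deletion"),
    random_edit(g, lib, "essential_gene", "own_promoter"),
    random_edit(g, lib, "essential_gene", "marker_promoter"),
    random_edit(g, lib, "essential_gene", "wt_restoring"))
  for (e in cases) {
    d <- design_cassette(e, g, lib)
    cass <- d$cassette
    ann <- cassette_annotations(cass)
    # annotations tile the cassette without gaps or overlaps
    expect_equal(ann$start[1], 1L)
    expect_equal(ann$start[-1], ann$end[-nrow(ann)] + 1L)
    expect_equal(ann$end[nrow(ann)], nchar(cassette_seq(cass)))
    # total length identity over the five structural blocks
    expect_equal(nchar(cassette_seq(cass)),
                 sum(vapply(cass$segments, function(s) nchar(s$seq), 0L)))
    # both HR3 copies byte-identical and within bounds
    expect_identical(cassette_part_seq(cass, "HR3_copy1"),
                     cassette_part_seq(cass, "HR3_copy2"))
    expect_gte(nchar(cass$hr3), 30L)
    expect_lte(nchar(cass$hr3), 50L)
    expect_equal(nchar(cassette_part_seq(cass, "HR1")), 100L)
    expect_equal(nchar(cassette_part_seq(cass, "HR2")), 100L)
    expect_false(any(d$report$checks$status == "fail"))
  }
})

test_that("designs are deterministic", {
  g <- plus_genome(802L)
  e <- edit_point_mutation("chr", 1500L, "A")
  d1 <- design_cassette(e, g, test_library)
  d2 <- design_cassette(e, g, test_library)
  expect_identical(cassette_seq(d1$cassette), cassette_seq(d2$cassette))
  expect_identical(d1$report$checks, d2$report$checks)
  expect_identical(d1$template$fragment5_with_overlaps,
                   d2$template$fragment5_with_overlaps)
})

test_that("validation flags injected faults", {
  g <- plus_genome(803L)
  set.seed(803)
  e <- random_edit(g, test_library, "point_mutation")
  d <- design_cassette(e, g, test_library)
  ok <- validate_design(d$cassette, g, test_library, design_config())
  expect_true(all(ok$checks$status != "fail"))
  # corrupt HR3 copy 2
  bad <- d$cassette
  i2 <- which(vapply(bad$segments, `[[`, "", "label") == "HR3_copy2")
  s2 <- bad$segments[[i2]]$seq
  substr(s2, 5, 5) <- if (substr(s2, 5, 5) == "A") "C" else "A"
  bad$segments[[i2]]$seq <- s2
  rep_bad <- validate_design(bad, g, test_library, design_config())
  ck <- rep_bad$checks
  expect_equal(ck$status[ck$name == "hr3_copies_identical"], "fail")
  expect_equal(ck$status[ck$name == "scarless_roundtrip"], "fail")
  # a genome with a pre-existing I-SceI site draws a warning
  gbad <- generate_fixture(fixture_spec(seed = 803L, plant_iscei = TRUE,
                                        minus_strand_frac = 0))
  set.seed(804)
  e2 <- random_edit(gbad, test_library, "point_mutation")
  d2 <- design_cassette(e2, gbad, test_library)
  ck2 <- d2$report$checks
  expect_equal(ck2$status[ck2$name == "iscei_absent_from_genome"], "warn")
})

test_that("non-recoded essential designs score lower integration odds", {
  g <- plus_genome(805L)
  set.seed(805)
  for (variant in c("own_promoter", "marker_promoter")) {
    e <- random_edit(g, test_library, "essential_gene", variant)
    d_rec <- design_cassette(e, g, test_library, recode = TRUE)
    d_non <- design_cassette(e, g, test_library, recode = FALSE)
    expect_gt(design_p_desired(d_rec$cassette),
              design_p_desired(d_non$cassette))
    # the naive design still round-trips; only its odds are worse
    expect_true(all(d_non$report$checks$status != "fail"))
  }
})

test_that("3xFLAG insertion lands once and in frame", {
  g <- plus_genome(806L)
  f <- g$features[g$features$kind == "CDS", ][1L, ]
  tag <- lib_part(test_library, "FLAG3x")$seq
  # insert immediately before the stop codon
  e <- edit_insertion("chr", f$end - 3L, tag)
  d <- design_cassette(e, g, test_library)
  final <- cleave_and_resolve(integrate_in_silico(g, d$cassette),
                              d$cassette, test_library)
  expect_identical(final$contigs, apply_edit(g, e)$contigs)
  expect_equal(nrow(scan_motif(final$contigs[["chr"]], tag, TRUE)), 1L)
  tagged <- substr(final$contigs[["chr"]], f$start, f$end + nchar(tag))
  wt <- translate_cds(feature_seq(g, f$feature_id))
  expect_equal(translate_cds(tagged),
               paste0(substr(wt, 1, nchar(wt) - 1),
                      "DYKDHDGDYKDHDIDYKDDDDK", "*"))
})
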