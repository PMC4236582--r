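test_that("wallace and nearest-neighbor Tm follow their formulas", {
  expect_equal(tm("AAAA", "wallace"), 8)
  expect_equal(tm("GCGC", "wallace"), 16)
  expect_error(tm("ACG", "wallace"), "shorter")
  # frozen hand-computed SantaLucia-unified sum for a fixed 20-mer
  # (dH = -153.10 kcal/mol, dS = -411.10 cal/mol/K, 250 nM primer,
  # 200 mM monovalent salt)
  expect_equal(tm("AGCTTGACCGGTATTGCCAT", "nn"), 60.0199, tolerance = 1e-4)
  # auto switches at 14 nt
  expect_equal(tm("AAAAAAAAAAAA", "auto"), tm("AAAAAAAAAAAA", "wallace"))
  expect_equal(tm(strrep("AG", 10), "auto"), tm(strrep("AG", 10), "nn"))
})

test_that("amplification primers anchor the region ends and meet Tm targets", {
  cfg <- design_config()
  set.seed(900)
  template <- random_seq(600, gc = 0.55)
  pr <- design_amplification_primers(template, region("t", 1, 600), cfg)
  expect_equal(pr$forward$seq,
               substr(template, 1, nchar(pr$forward$seq)))
  expect_equal(pr$reverse$seq,
               revcomp(substr(template, 601 - nchar(pr$reverse$seq), 600)))
  expect_gte(pr$forward$tm_anneal, cfg$tm_target)
  expect_gte(pr$reverse$tm_anneal, cfg$tm_target)
  expect_lte(abs(pr$forward$tm_anneal - pr$reverse$tm_anneal), cfg$tm_delta)
  # primers re-verify against the template by exact match
  expect_equal(scan_motif(template, pr$forward$seq)$pos, 1L)
  expect_equal(scan_motif(template, revcomp(pr$reverse$seq))$pos,
               601L - nchar(pr$reverse$seq))
  # anneal length equals the brute-force minimal length reaching the Tm
  lens <- cfg$primer_min_len:cfg$primer_max_len
  brute <- lens[vapply(lens, function(L) {
    tm(substr(template, 1, L), "auto", cfg) >= cfg$tm_target
  }, TRUE)][1]
  expect_lte(brute, nchar(pr$forward$seq))  # balancing may extend further
  expect_gte(tm(substr(template, 1, brute), "auto", cfg), cfg$tm_target)
})

test_that("AT-rich templates need longer primers than GC-rich ones", {
  cfg <- design_config()
  set.seed(901)
  at_rich <- random_seq(300, gc = 0.32)
  gc_rich <- random_seq(300, gc = 0.68)
  p_at <- design_amplification_primers(at_rich, region("t", 1, 300), cfg)
  p_gc <- design_amplification_primers(gc_rich, region("t", 1, 300), cfg)
  expect_gt(nchar(p_at$forward$seq), nchar(p_gc$forward$seq))
})

test_that("assembly length arithmetic is exact", {
  expect_equal(assembly_total_length(c(100, 100), 20), 180L)
  expect_equal(assembly_total_length(c(21, 405, 81, 81, 22), 0), 610L)
  expect_equal(assembly_total_length(c(405, 81, 69), 0), 555L)
})

test_that("plan_assembly validates junctions and reproduces the product", {
  set.seed(902)
  ov <- 20L
  a <- random_seq(120); b <- random_seq(150); c3 <- random_seq(90)
  b2 <- paste0(substr(a, 101, 120), b)
  c2 <- paste0(substr(b2, nchar(b2) - ov + 1L, nchar(b2)), c3)
  plan <- plan_assembly(list(A = a, B = b2, C = c2), ov)
  expect_equal(plan$total_length, 120L + 170L + 110L - 2L * ov)
  expect_equal(nchar(plan$product), plan$total_length)
  expect_equal(plan$product, paste0(a, b, c3))
  expect_false(plan$ambiguous)
  # mismatched junction
  expect_error(plan_assembly(list(A = a, C = c2), ov), "junction")
  expect_error(plan_assembly(list(A = a, B = b2, C = c2), 10), "overlap_len")
})

test_that("designed template fragments assemble back into the cassette", {
  g <- plus_genome(903L)
  set.seed(903)
  e <- random_edit(g, test_library, "essential_gene", "marker_promoter")
  d <- design_cassette(e, g, test_library)
  plan <- d$template$plan
  expect_false(plan$ambiguous)
  # the interior of the assembled product (backbone trimmed off both
  # ends) is exactly the designed cassette
  bb <- pha_backbone()
  interior <- substr(plan$product, nchar(bb) + 1L,
                     nchar(plan$product) - d$template$overlap_len)
  expect_equal(interior, cassette_seq(d$cassette))
})
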