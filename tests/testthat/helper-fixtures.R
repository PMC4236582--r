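# Shared fixtures built in code at test time.

test_table <- codon_table()
test_library <- default_element_library()

# a small plus-strand-only genome for targeted geometry tests
plus_genome <- function(seed = 101L) {
  generate_fixture(fixture_spec(seed = seed, n_genes = 3L,
                                minus_strand_frac = 0))
}

# mixed-strand genome for round-trip suites
mixed_genome <- function(seed = 202L, n_genes = 4L) {
  generate_fixture(fixture_spec(seed = seed, n_genes = n_genes,
                                minus_strand_frac = 0.4))
}

syn_of <- function(codon, table = test_table) {
  names(table$code)[table$code == table$code[[codon]]]
}

random_cds_fragment <- function(n_codons, table = test_table) {
  sense <- names(table$code)[table$code != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# parts of the given roles that must be absent from a resolved genome
scar_roles <- c("marker", "terminator", "isceI_site")

contains_scar <- function(genome, library = test_library) {
  for (p in lib_part(library)) {
    if (!p$role %in% scar_roles) next
    for (s in genome$contigs) {
      if (nrow(scan_motif(s, p$seq, both_strands = TRUE)) > 0L) return(TRUE)
    }
  }
  FALSE
}
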