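# Deterministic synthetic-genome fixture generator: toy bacterial
# contigs with valid CDS features (initiation codon, no internal stops,
# terminal stop), used throughout the test-suite and examples in place
# of real loci.

#' Fixture specification
#'
#' @param seed integer seed; identical specs generate identical genomes.
#' @param n_genes number of CDS features.
#' @param gene_len_range codon-count range per gene (codons incl. start
#'   and stop).
#' @param intergenic_range intergenic spacer length range (bp); the
#'   contig additionally gets margins of at least the largest spacer at
#'   both ends so edits near gene boundaries have flanking sequence.
#' @param gc GC fraction of intergenic sequence.
#' @param minus_strand_frac fraction of genes placed on the minus strand.
#' @param plant_iscei plant one I-SceI site (`site` below) in an
#'   intergenic region - a negative-control pathology.
#' @param site the site sequence planted when `plant_iscei` is TRUE.
#' @return a `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 4L,
                         gene_len_range = c(150L, 260L),
                         intergenic_range = c(420L, 650L),
                         gc = 0.5, minus_strand_frac = 0.25,
                         plant_iscei = FALSE,
                         site = "TAGGGATAACAGGGTAAT") {
  stopifnot(n_genes >= 1L, gene_len_range[1] >= 20L,
            gene_len_range[1] <= gene_len_range[2],
            intergenic_range[1] >= 50L,
            intergenic_range[1] <= intergenic_range[2],
            gc > 0, gc < 1, minus_strand_frac >= 0, minus_strand_frac <= 1)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 gene_len_range = as.integer(gene_len_range),
                 intergenic_range = as.integer(intergenic_range),
                 gc = gc, minus_strand_frac = minus_strand_frac,
                 plant_iscei = isTRUE(plant_iscei), site = nuc(site)),
            class = "fixture_spec")
}

random_cds <- function(n_codons, table) {
  sense <- names(table$code)[table$code != "*"]
  stops <- names(table$code)[table$code == "*"]
  body <- sample(sense, n_codons - 2L, replace = TRUE)
  paste(c("ATG", body, sample(stops, 1L)), collapse = "")
}

#' Generate a synthetic genome fixture
#'
#' @param spec a [fixture_spec()].
#' @param table [codon_table()].
#' @return a [genome_record()] with one contig (`chr`) and `gene01`,
#'   `gene02`, ... CDS features.
#' @export
generate_fixture <- function(spec = fixture_spec(), table = codon_table()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    rint <- function(rg) sample(rg[1]:rg[2], 1L)
    margin <- spec$intergenic_range[2]
    pieces <- random_seq(margin, spec$gc)
    feats <- empty_features()
    pos <- nchar(pieces)
    for (i in seq_len(spec$n_genes)) {
      cds <- random_cds(rint(spec$gene_len_range), table)
      strand <- if (runif(1) < spec$minus_strand_frac) "-" else "+"
      gstart <- pos + 1L
      gend <- pos + nchar(cds)
      pieces <- paste0(pieces, if (strand == "+") cds else revcomp(cds))
      feats <- rbind(feats, data.frame(
        feature_id = sprintf("gene%02d", i), contig = "chr",
        start = gstart, end = gend, strand = strand, kind = "CDS",
        product = sprintf("synthetic protein %02d", i),
        stringsAsFactors = FALSE))
      pos <- gend
      ig <- random_seq(rint(spec$intergenic_range), spec$gc)
      pieces <- paste0(pieces, ig)
      pos <- pos + nchar(ig)
    }
    pieces <- paste0(pieces, random_seq(margin, spec$gc))
    if (spec$plant_iscei) {
      # drop the site into the final margin, away from every gene
      at <- nchar(pieces) - margin %/% 2L
      pieces <- paste0(substr(pieces, 1L, at - 1L), spec$site,
                       substr(pieces, at + nchar(spec$site),
                              nchar(pieces)))
    }
    genome_record(c(chr = pieces), feats, table)
  })
}

#' Draw a random edit for a fixture genome
#'
#' Picks an edit kind (and, for essential-gene edits, a variant) and a
#' compatible random location on the fixture. Used by the randomized
#' round-trip suites.
#'
#' @param genome a [genome_record()] from [generate_fixture()].
#' @param library an [element_library()] (supplies the insertion tag).
#' @param kind one of `point_mutation`, `insertion`, `deletion`,
#'   `essential_gene`, or `"random"`.
#' @param variant essential variant or `"random"`.
#' @param table [codon_table()].
#' @return an [edit_spec].
#' @export
random_edit <- function(genome, library = default_element_library(),
                        kind = "random", variant = "random",
                        table = codon_table()) {
  kinds <- c("point_mutation", "insertion", "deletion", "essential_gene")
  if (kind == "random") kind <- sample(kinds, 1L)
  fe <- genome$features[genome$features$kind == "CDS", , drop = FALSE]
  stopifnot(nrow(fe) > 0L)
  f <- fe[sample(nrow(fe), 1L), ]
  switch(kind,
    point_mutation = {
      pos <- sample(f$start:f$end, 1L)
      old <- substr(genome$contigs[[f$contig]], pos, pos)
      new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      edit_point_mutation(f$contig, pos, new)
    },
    insertion = {
      tag <- lib_part(library, "FLAG3x")$seq
      small <- sample(c(TRUE, FALSE), 1L)
      ins <- if (small) random_seq(sample(6:18, 1L)) else tag
      edit_insertion(f$contig, sample(f$start:f$end, 1L), ins)
    },
    deletion = {
      len <- sample(30:400, 1L)
      start <- sample(f$start:(f$end - 10L), 1L)
      edit_deletion(f$contig, start, start + len - 1L)
    },
    essential_gene = {
      if (variant == "random") {
        variant <- sample(c("own_promoter", "marker_promoter",
                            "wt_restoring"), 1L)
      }
      n_codons <- (f$end - f$start + 1L) %/% 3L
      # keep the codon-aligned HR3 window and the recoded segment clear
      # of both CDS ends
      r <- sample(16:(n_codons - 16L), 1L)
      cds <- feature_seq(genome, f$feature_id)
      from <- substr(cds, 3L * r - 2L, 3L * r)
      syn <- setdiff(synonyms(from, table), from)
      to <- if (length(syn)) sort(syn)[1L] else revcomp(from)
      edit_essential(f$feature_id, r, to, variant,
                     rbs_boost = variant == "marker_promoter")
    })
}
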