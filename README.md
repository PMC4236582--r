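# scarless

Design automation for **scarless two-step genome editing in bacteria**
(*E. coli*, *Salmonella* and relatives): lambda-Red-mediated integration
of a selectable mutation cassette, followed by I-SceI counter-selection
and RecA-mediated resolution that excises the selection machinery and
leaves only the intended edit — no marker, no recognition site, no scar.

It is written for strain engineers who design these cassettes by hand
today: given a genome (GenBank or FASTA + feature table), an edit
specification and an element library, the package produces a fully
annotated, validated cassette, the template-plasmid assembly fragments
and primers, and an in-silico proof that the two recombination steps
resolve to exactly the intended genome.

## The cassette model

A mutation cassette is the linear fragment

```
HR1 — fragment5 — [TT — I-SceI site — marker] — fragment3 — HR2
```

* **HR1/HR2** (100 bp each) target the cassette to the locus;
* **HR3**, a 30–50 bp window spanning the desired modification, is
  duplicated at the 3' end of fragment5 and the 5' end of fragment3 and
  flanks the excisable core;
* the core carries a double transcription terminator (**TT**) that
  shields the 18 bp **I-SceI** site from read-through transcription,
  plus a selection **marker**.

After integration (step one, selected on the marker), induction of
I-SceI cuts the chromosome; survivors have resolved the break by a
single crossover between the two identical HR3 copies, which removes
everything between them (step two). Because the edit sits inside HR3
(or immediately after it), the resolved genome carries the mutation and
nothing else.

Two further ideas from this design tradition are implemented
quantitatively:

* **Synonymous recoding for essential genes.** Interrupting an
  essential gene kills the intermediate, so the cassette carries an
  extra segment that reconstitutes a complete ORF — rewritten codon by
  codon with synonymous codons (objective: maximal per-codon nucleotide
  Hamming distance, shared windows with the genomic copy capped at
  `w_max` = 14 bp) so it encodes the same protein but cannot recombine
  with the target. The package models why: with the second crossover
  uniform over bases lying in identity runs of at least *w* bp,
  `p_desired_integration` is the fraction of eligible bases 3' of the
  last mutated position. Recoding removes the wrong-side eligible bases
  and drives that probability toward 1.
* **Silent RBS boosting.** For ORFs restored downstream of the marker,
  `silent_rbs_boost` introduces silent mutations in the marker's 3' end
  that maximize the Shine-Dalgarno consensus score (AGGAGG, spacer
  4–13 nt) of the junction — provably optimal over all fully-silent
  variants, marker protein unchanged.

## Worked example

```r
library(scarless)

g   <- generate_fixture(fixture_spec(seed = 42))   # synthetic 4-gene genome
lib <- default_element_library()

# silent Ser codon swap (TCG -> TCT) at residue 40 of an essential gene,
# ORF reconstituted under the gene's own promoter during editing
e <- edit_essential("gene02", residue = 40, to_codon = "TCT",
                    variant = "own_promoter")
d <- design_cassette(e, g, lib)
d$cassette
#> <mutation_cassette> essential_gene (own_promoter) - 1849 bp, HR3 39 bp, inside_hr3
#>   HR1                     1..100    hr
#>   F5                    101..261    target
#>   HR3_copy1             262..300    hr3
#>   RECODED               301..759    recoded
#>   SPACER_K259002a       760..774    spacer
#>   ...
#>   ISceI_site            872..889    isceI_site
#>   MARKER_cat            890..1549   marker
#>   HR3_copy2            1550..1588   hr3
#>   F3                   1589..1749   target
#>   HR2                  1750..1849   hr
d$report
#> <design_report>
#>   [PASS] hr1_unique                 1 hits
#>   [PASS] hr2_unique                 1 hits
#>   [PASS] iscei_unique_in_cassette   1 sites
#>   ...
#>   [PASS] recoded_shared_window      9 bp (w_max 14)
#>   [PASS] p_desired_integration      0.934 (threshold 0.90)
#>   [PASS] scarless_roundtrip
```

Reading the report: the 39 bp HR3 window (snapped to codon boundaries)
carries the TCT codon; the 459 bp recoded segment completes the ORF and
shares at most a 9 bp exact window with the genomic copy, so 93.4% of
model-eligible crossover positions transfer the mutation. The final
check replays both recombination steps in silico:

```r
final <- cleave_and_resolve(integrate_in_silico(g, d$cassette), d$cassette, lib)
identical(final$contigs, apply_edit(g, e)$contigs)
#> [1] TRUE
```

`write_design(d, "out/")` emits the annotated GenBank map, template
fragment FASTA, primer TSV, JSON report and config snapshot. A thin CLI
wraps the same functions:

```sh
Rscript inst/cli/scarless.R design --genome genome.gb \
    --edit inst/extdata/example_edit.json --out out/
```

Insertions (`edit_insertion`, e.g. a 3xFLAG tag before a stop codon),
deletions (`edit_deletion`) and point mutations (`edit_point_mutation`)
use the same pipeline; the two other essential-gene variants
(`marker_promoter`, optionally with `rbs_boost = TRUE`, and
`wt_restoring`) change where the recoded segment sits and whether the
intermediate expresses the edited or the wild-type protein.

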