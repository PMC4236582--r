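---
title: "Designing scarless genome-editing cassettes: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing scarless genome-editing cassettes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scarless)
```

This vignette is the package's account of the science it implements:
the two-step editing procedure it automates, the quantitative models
behind its design rules, every tunable parameter with its default and
rationale, the numerical and geometric choices made where the design
space was genuinely open, and what the synthetic-fixture test-suite
does and does not establish about real genomes.

## The procedure being designed for

Two-step scarless editing replaces a genomic span with a *mutation
cassette* by lambda-Red recombination, selecting on an antibiotic
marker; a meganuclease (I-SceI, 18 bp recognition site, absent from
wild-type enterobacterial genomes) is then induced to cut the single
site carried by the cassette. The double-strand break is lethal unless
resolved, and the cassette offers exactly one homologous resolution: a
crossover between two identical copies of a short window (HR3) that
flank the cleavable core. Resolution deletes the core — terminators,
site and marker — leaving only the edit carried within (or immediately
after) HR3. The design problem is to choose all of these sequences so
that both recombination steps are uniquely targeted, the intermediate
is viable (critical for essential genes), and the probability that
integration actually transfers the mutation is high.

`design_cassette()` assembles, for every edit kind, the segment order

```
HR1 | F5 | HR3_copy1 [| RECODED] | spacers/terminators | I-SceI | marker
    [| RECODED] | HR3_copy2 [| MUTATION or INSERT] | F3 | HR2
```

and `validate_design()` re-derives every claim (uniqueness of anchors,
single site, HR3 identity, ORF integrity, shared-window bound,
integration probability, and a full in-silico round trip against
`apply_edit()`).

## Coordinates

All coordinates, internal and user-facing, are 1-based inclusive on
the plus strand — the native R, IRanges and GenBank convention. Using
one convention everywhere removes the class of off-by-one errors that
motivates split conventions; the cost (inclusive-end arithmetic) is
idiomatic in this language. Minus-strand CDS targets are handled by
designing in the feature-strand frame and reverse-complementing the
finished cassette, so emitted cassettes are always plus-strand.

## HR3 placement rules

HR3 defaults to 40 bp within enforced bounds [30, 50] — long enough
for RecA-mediated resolution, short enough to keep unwanted crossover
positions rare.

* **Point mutations** centre the edited span, ties toward the 5' side
  (a single mutation in a 40 bp window sits at position 20).
* **Deletions** fuse the flanks: the last 20 bp before and the first
  20 bp after the deleted span.
* **Insertions** are embedded inside HR3 when the insert plus at least
  5 bp of context per side fits within 50 bp; longer inserts (e.g. a
  66 bp 3xFLAG tag) are placed immediately after HR3 copy 2, with HR3
  the 40 bp of target ending at the insertion junction.
* **Essential-gene edits** snap the window to codon boundaries (13
  codons = 39 bp by default) so the adjoining recoded segment stays in
  frame; the edited codon is centred. The wild-type-restoring variant
  instead uses a wild-type window ending at the codon boundary
  immediately before the edited codon, and the mutation rides
  immediately after HR3 copy 2.

## Essential genes: where the recoded segment goes

The intermediate genome must express a functional copy of an essential
gene throughout the procedure, so the cassette restores a complete ORF
using a synonymously recoded segment. Geometry follows from which
promoter must drive that ORF:

* `own_promoter`: the restored ORF must be contiguous with the native
  promoter, so the recoded remainder (HR3 window end through the stop
  codon) sits at the end of fragment5, 5' of the selection core. The
  intermediate ORF is genomic 5' part + mutated HR3 + recoded
  remainder and translates to the edited protein.
* `marker_promoter`: the restored ORF reads out of the constitutive
  promoter associated with the marker, so the recoded head (start
  codon through the codon before the HR3 window) sits after the
  marker, 5' of HR3 copy 2. This suits first-genes-in-operons (no
  polar effects). The junction gap between the marker stop codon and
  the restored start codon defaults to 0 nt (`cat_orf_gap`,
  configurable and recorded in reports) — the exact published junction
  geometry is not printed, and translational coupling argues for
  adjacency. With `rbs_boost = TRUE` the marker's last 8 codons are
  silently mutated to maximize the Shine-Dalgarno score of that
  junction.
* `wt_restoring`: as `own_promoter` but the recoded remainder encodes
  the *wild-type* protein and HR3 is wild-type; the mutation is placed
  immediately after HR3 copy 2, so the gene keeps wild-type function
  until resolution installs the edit. This is the variant of choice
  when the gene product itself (e.g. RecA) is needed for the
  resolution step.

In all three variants both HR3 copies are byte-identical (including
the edit, except in `wt_restoring`, where both are wild-type), because
resolution requires perfect duplicates.

## The recoder

`recode_synonymous()` replaces every codon whose amino acid has more
than one codon with a *different* synonymous codon. The objective is
per-codon maximal nucleotide Hamming distance — the most direct proxy
for "cannot recombine with the genomic copy". Ties break by
codon-usage frequency when a table is supplied (`ecoli_codon_usage()`
ships standard reference values), then lexicographically; tie-breaking
is the only role of the usage table, so recoded fragments are
deterministic. Two hard constraints are then repaired by local
re-choice, scanning left to right: no forbidden motif (the design
pipeline forbids the library's I-SceI site, screened on both strands)
and `max_shared_window(recoded, original) <= w_max`.

`w_max` defaults to 14 bp: comfortably below both the 30 bp lower
bound of HR3 ("sufficient for RecA-mediated recombination") and the
~20 bp pairing scale of lambda-Red, with margin. Runs of Met/Trp
codons (single-codon families) longer than `w_max` are genuinely
infeasible and raise an error naming the span rather than silently
under-diverging.

`max_shared_window` is the longest common substring, computed by
binary search over shared k-mer sets; the test-suite checks it against
an independent diagonal-scan implementation.

## The integration-outcome model

Lambda-Red integration places a crossover in each homology arm. On the
arm that carries the ORF-restoring segment, any position of sufficient
donor-genome identity can host the second crossover; crossovers that
land 5' of the last mutated position leave the mutation behind
(regenerating wild type after resolution), which is exactly the
failure mode the synonymous-codon strategy removes.

`p_desired_integration(mask, mutations, w)` formalizes this with the
minimal assumptions the qualitative argument supports: identity is a
per-base boolean mask (positional alignment of donor arm to target —
legitimate because the donor is designed from the target; edit bases
are masked false, inserted bases have no counterpart and are masked
false, and deletion-junction-adjacent bases are masked false because a
pairing window cannot span a fusion junction); crossovers require
containment in an identity run of at least `w` bases
(`w_integration`, default 20 bp — a lambda-Red-scale pairing window,
configurable, not a published value); and position is uniform over
eligible bases. The returned probability is the eligible fraction 3'
of the last mutation.

Per design variant the modelled arm is the one carrying the recoded
segment: the 3' arm for `marker_promoter` and all non-essential kinds,
the mirrored 5' arm for `own_promoter` (the mask and mutation
positions are reversed so the same statistic applies), and the 3' arm
for `wt_restoring`, whose edit sits just after HR3 copy 2. Recoded
designs typically score 0.93–1.0 where the matched naive
(non-recoded, `recode = FALSE`) geometry scores 0.4–0.7; the
dominance is strict whenever the restorable segment is at least `w`
bp, and the test-suite asserts it on 50 matched designs.
`p_threshold` (default 0.9) turns the statistic into a report warning.

The model is deliberately minimal: it does not weight crossover
position by local GC, length beyond the `w` cutoff, or mismatch
tolerance within pairing windows, and it treats the two arms
independently. It ranks designs; it does not predict colony counts.

## Resolution model

Resolution is modelled as a single deterministic crossover between the
two identical HR3 duplicates: one copy retained, interior excised.
Alternative resolutions through residual homology elsewhere are not
simulated; `validate_design()` instead warns when it can see the
preconditions for them (non-unique anchors, pre-existing I-SceI sites,
non-identical copies). The in-silico step requires exactly one site
and exactly two HR3 occurrences and verifies the excised genome is
free of marker, terminator and site sequence.

## RBS scoring and the silent boost

`rbs_score()` slides a consensus (default AGGAGG — the classic
Shine-Dalgarno core; configurable) over the window upstream of a start
codon, counting matches at every placement whose spacer lies in
[4, 13] nt, ties to the smallest spacer. Score units are matched
positions (0–6 for the default consensus); this is an ordinal design
score, not a binding-energy model, and the package deliberately ships
no free-energy calculator.

`silent_rbs_boost()` finds the exact optimum over all fully-silent
variants of an in-frame tail by observing that, for a fixed placement,
each codon overlapping the consensus can be optimized independently;
scanning all placements therefore finds the global maximum without
enumeration. Synonyms that tie prefer the original codon, so the
boost makes the fewest mutations that achieve the maximal score; the
mutation count depends on the marker tail, since the operation
implements the boosting procedure rather than any fixed set of bases.

## Secondary-structure screen

Full thermodynamic folding is out of scope. Spacer regions are instead
screened for maximal perfect inverted repeats (`hairpin_screen`,
default stem >= 8 bp, loop 3–10 nt), the structural motif terminators
are built from and the main hairpin-forming signal at these lengths. A
hit is maximal when its stem extends neither outward nor inward
(without shrinking the loop below the minimum). This is a surrogate
for an energy-based screen, and reported hits are warnings, not
errors.

## Primers and assembly

Amplification primers anchor the amplicon ends and grow (18–35 nt)
until the melting temperature reaches 60 degC, then the pair is
balanced to within 3 degC — conventional, configurable values, not
derived from any publication. Tm uses the Wallace rule below 14 nt and
SantaLucia (1998) unified nearest-neighbor parameters otherwise, with
a 16.6 log10[Na+] correction at an effective monovalent ionic
strength of 200 mM (a PCR-buffer-equivalent default) and 250 nM
primer. `plan_assembly()` validates Gibson-style junctions (default
20 bp overlaps, bounds [15, 40]), errors on duplicate junction
sequences and flags junctions recurring anywhere in the product as
mis-assembly risks; the template-plasmid fragments produced for every
design reassemble byte-exactly into backbone + cassette, which the
test-suite asserts. Because the published selection-cassette composition
reuses its two spacers at both ends of the terminator block, the block
is built from distinct halves of each spacer part — full duplicates
would themselves create the ambiguous-junction situation the planner
rejects.

## Element library and defaults

The bundled `default_element_library()` carries the canonical 18 bp
I-SceI recognition site as an external-knowledge default plus
deterministic *synthetic placeholder* sequences for the named
terminator/spacer/marker parts (their published identities are part
IDs, not sequences) and a fixed-codon 3xFLAG tag. Every placeholder is
labelled as such; real parts are supplied through a library FASTA with
`role=`/`name=` header tags, and nothing in the pipeline or the tests
depends on the placeholder bases — only on the declared roles and on
the invariants (single site part; marker parts are complete ORFs).

## Determinism and numerical choices

Designs contain no randomness: identical (edit, genome, library,
config) inputs produce byte-identical cassettes, reports and bundles
(hash-stamped with config and library hashes for provenance). All
randomness lives in the fixture generator and test-suite, always under
explicit seeds. Degenerate inputs are rejected at construction
(ambiguity codes, empty motifs, out-of-bounds features), and every
tie-break in the package (codon choice, HR3 centring, RBS placement,
hairpin maximality) is specified and tested rather than left to
iteration order.

## What the synthetic fixtures do and do not show

`generate_fixture()` produces uniform-composition contigs with valid,
well-separated CDS features on both strands and generous intergenic
margins. It emulates the *structural* situation of a bacterial locus —
unique 100 bp anchors, codon structure, strand handling — and supports
the round-trip, recoding and probability suites at scale (hundreds of
randomized designs). It does not emulate repeated sequence families,
operonic gene overlap, skewed GC, or real promoter/RBS context. The
passing suites therefore establish the correctness of the design
algebra and models, not performance on pathological genomic repeats;
on real genomes the anchor-uniqueness and pre-existing-site checks in
`validate_design()` are the guard rails. Problem sizes used by the
suites (3–4-gene fixtures of ~6–8 kb, 100 round-trip edits, 1000
model masks, exhaustive oracles bounded at ~30k enumerants) were
chosen as the smallest sizes that exercise every code path and
geometry.

## Known limitations

* Circular-sequence, origin-spanning features are unsupported; maps
  are emitted linearized.
* One edit per cassette; no multi-edit batching.
* The integration model ranks designs and does not predict absolute
  efficiencies; cleavage efficiency vs transcription level is
  represented structurally (0/1/2 terminators), not quantitatively.
* Promoter strength and expression level are out of scope; the
  marker-promoter variant is modelled structurally (ORF contiguity and
  RBS score).
* Off-target priming beyond exact-match multiplicity and thermodynamic
  primer-dimer screens are not performed.
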