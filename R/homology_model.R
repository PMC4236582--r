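# Crossover-position model of lambda-Red integration, and in-silico
# execution of the integration / cleavage / resolution steps.
#
# The donor arm that carries the desired mutation(s) is aligned base-by-
# base to its genomic counterpart (the donor is designed from the target,
# so the alignment is positional). A crossover can initiate wherever the
# two molecules are identical over at least w consecutive bases; crossover
# position is modelled as uniform over those eligible bases. A crossover
# transfers all mutations only when it lies 3' of the last mutated
# position, so recoding the region 5' of the mutations (destroying
# identity there) concentrates eligible bases on the desired side.

#' Identity mask between a donor arm and its genomic counterpart
#'
#' @param donor,target equal-length nucleotide strings (positional
#'   alignment; the edit positions differ by construction).
#' @param label free-text region label.
#' @return an `identity_mask`: logical vector (TRUE = identical) with
#'   attributes `label` and `mutations` (positions where the donor
#'   carries the edit).
#' @export
identity_mask <- function(donor, target, label = "donor_arm") {
  donor <- nuc(donor, "donor"); target <- nuc(target, "target")
  if (nchar(donor) != nchar(target)) {
    stop("donor and target must be the same length (positional alignment)",
         call. = FALSE)
  }
  m <- strsplit(donor, "")[[1]] == strsplit(target, "")[[1]]
  structure(m, label = label, class = "identity_mask")
}

as_mask <- function(x) {
  if (inherits(x, "identity_mask")) return(as.logical(x))
  stopifnot(is.logical(x))
  x
}

#' Maximal identity runs long enough to pair
#'
#' @param mask logical identity vector (or [identity_mask()]).
#' @param w minimal pairing window (bp), >= 1.
#' @return data.frame of maximal TRUE runs with length >= `w` (`start`,
#'   `end`, 1-based inclusive), in coordinate order.
#' @export
eligible_segments <- function(mask, w) {
  m <- as_mask(mask)
  w <- as.integer(w)
  if (is.na(w) || w < 1L) stop("w must be >= 1", call. = FALSE)
  if (length(m) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= w
  out <- data.frame(start = starts[keep], end = ends[keep])
  rownames(out) <- NULL
  out
}

#' Probability that integration transfers all mutations
#'
#' With the second crossover placed uniformly over the eligible bases
#' (bases inside maximal identity runs of length >= `w`), returns the
#' fraction of eligible bases lying 3' of the last mutated position:
#' exactly those crossovers leave every mutation on the integrated side.
#' Crossovers between two mutations count as failures.
#'
#' @param mask logical identity vector or [identity_mask()].
#' @param mutation_positions 1-based positions of the mutated bases; the
#'   mask must be FALSE there.
#' @param w minimal pairing window (bp).
#' @return probability in `[0, 1]`.
#' @export
p_desired_integration <- function(mask, mutation_positions, w) {
  m <- as_mask(mask)
  mut <- as.integer(mutation_positions)
  if (length(mut) == 0L) stop("no mutation positions given", call. = FALSE)
  if (any(mut < 1L | mut > length(m))) {
    stop("mutation positions outside the mask", call. = FALSE)
  }
  if (any(m[mut])) {
    stop("mask must be FALSE at every mutation position", call. = FALSE)
  }
  seg <- eligible_segments(m, w)
  n_elig <- sum(seg$end - seg$start + 1L)
  if (n_elig == 0L) {
    stop("design infeasible: no identity run of length >= ", w,
         " - integration impossible under the model", call. = FALSE)
  }
  last_mut <- max(mut)
  n_good <- 0L
  for (i in seq_len(nrow(seg))) {
    lo <- max(seg$start[i], last_mut + 1L)
    if (lo <= seg$end[i]) n_good <- n_good + seg$end[i] - lo + 1L
  }
  n_good / n_elig
}

#' Integrate a mutation cassette in silico
#'
#' Emulates lambda-Red replacement of the genomic span between the HR1
#' and HR2 anchor sites by the cassette. HR1 and HR2 must each occur
#' exactly once in the genome, in order, on the plus strand.
#'
#' @param genome a [genome_record()].
#' @param cassette a `mutation_cassette` (see [design_cassette()]).
#' @return the intermediate [genome_record()]: the span from the start of
#'   the HR1 site to the end of the HR2 site replaced by the full
#'   cassette, with cassette part annotations added as features.
#' @export
integrate_in_silico <- function(genome, cassette) {
  stopifnot(inherits(genome, "genome_record"),
            inherits(cassette, "mutation_cassette"))
  hr1 <- cassette_part_seq(cassette, "HR1")
  hr2 <- cassette_part_seq(cassette, "HR2")
  contig <- cassette$target_contig
  s <- genome$contigs[[contig]]
  if (is.null(s)) stop("cassette targets unknown contig ", contig,
                       call. = FALSE)
  h1 <- scan_motif(s, hr1)$pos
  h2 <- scan_motif(s, hr2)$pos
  if (length(h1) != 1L || length(h2) != 1L) {
    stop("targeting error: HR1 occurs ", length(h1), "x and HR2 occurs ",
         length(h2), "x in ", contig, " (each must occur exactly once)",
         call. = FALSE)
  }
  if (h2 <= h1) {
    stop("targeting error: HR2 site does not lie 3' of HR1", call. = FALSE)
  }
  ann <- cassette_annotations(cassette)
  nf <- data.frame(feature_id = paste0("cassette_", ann$label),
                   contig = contig, start = ann$start, end = ann$end,
                   strand = "+", kind = "misc", product = ann$label,
                   stringsAsFactors = FALSE)
  splice_contig(genome, contig, h1, h2 + nchar(hr2) - 1L,
                cassette_seq(cassette), new_features = nf)
}

#' Cleave at the I-SceI site and resolve between the HR3 duplicates
#'
#' Emulates I-SceI counter-selection followed by a single RecA crossover
#' between the two identical HR3 copies: one copy is retained and
#' everything between the copies (terminators, I-SceI site, marker, and
#' any recoded segment) is excised. The intermediate must contain exactly
#' one I-SceI site and exactly two identical HR3 copies flanking it.
#'
#' @param intermediate the [genome_record()] returned by
#'   [integrate_in_silico()].
#' @param cassette the designed `mutation_cassette` (supplies the HR3
#'   sequence).
#' @param library the [element_library()] (supplies the I-SceI site).
#' @return the resolved [genome_record()].
#' @export
cleave_and_resolve <- function(intermediate, cassette, library) {
  stopifnot(inherits(intermediate, "genome_record"),
            inherits(cassette, "mutation_cassette"),
            inherits(library, "element_library"))
  contig <- cassette$target_contig
  s <- intermediate$contigs[[contig]]
  site <- iscei_site(library)
  hits <- scan_motif(s, site, both_strands = TRUE)
  if (nrow(hits) != 1L) {
    stop("cleavage error: ", nrow(hits), " I-SceI site(s) in ", contig,
         " (exactly one required)", call. = FALSE)
  }
  hr3 <- cassette$hr3
  occ <- scan_motif(s, hr3)$pos
  if (length(occ) != 2L) {
    stop("resolution error: HR3 occurs ", length(occ),
         "x in the intermediate (exactly two identical copies required)",
         call. = FALSE)
  }
  if (!(hits$pos[1L] > occ[1L] + nchar(hr3) - 1L && hits$pos[1L] < occ[2L])) {
    stop("resolution error: I-SceI site does not lie between the HR3 ",
         "copies", call. = FALSE)
  }
  # retain copy 1, excise through the end of copy 2
  resolved <- splice_contig(intermediate, contig, occ[1L] + nchar(hr3),
                            occ[2L] + nchar(hr3) - 1L, "")
  rs <- resolved$contigs[[contig]]
  if (nrow(scan_motif(rs, site, both_strands = TRUE)) != 0L) {
    stop("resolution error: I-SceI site persists after excision",
         call. = FALSE)
  }
  resolved
}
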