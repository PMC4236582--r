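# Turning an edit specification into a validated mutation cassette:
#   HR1 | fragment5 | selection core | fragment3 | HR2
# where the two HR3 copies (3' end of fragment5, 5' end of fragment3)
# span the desired modification and flank the excisable core, and
# essential-gene designs add a synonymously recoded ORF-restoring
# segment on the side dictated by the promoter that must drive the gene
# during the procedure.

INSERTION_MIN_CTX <- 5L  # minimum HR3 context flanking an embedded insert

#' Edit specifications
#'
#' Declarative descriptions of the desired genomic change. All
#' coordinates are 1-based inclusive on the plus strand; essential-gene
#' edits are specified on the feature strand via residue index.
#'
#' @param contig contig id.
#' @param start for a point mutation, the first replaced base; for a
#'   deletion, the first deleted base.
#' @param replacement replacement bases (same length as the replaced
#'   window; may differ at several positions).
#' @param after insertion point: the new sequence is inserted after this
#'   base.
#' @param insert inserted sequence.
#' @param end last deleted base.
#' @param feature_id CDS feature to edit (essential-gene designs).
#' @param residue 1-based codon index of the edited codon.
#' @param to_codon replacement codon (on the feature strand).
#' @param variant essential-gene design variant: `own_promoter` and
#'   `marker_promoter` reconstitute the *edited* ORF in the intermediate
#'   (under the gene's own promoter or the constitutive promoter of the
#'   selection marker); `wt_restoring` keeps the intermediate ORF
#'   wild-type and places the mutation immediately after HR3.
#' @param rbs_boost for `marker_promoter`: silently mutate the marker 3'
#'   end to strengthen the ribosome-binding site of the restored ORF.
#' @return an `edit_spec` object.
#' @name edit_spec
NULL

#' @rdname edit_spec
#' @export
edit_point_mutation <- function(contig, start, replacement) {
  replacement <- nuc(replacement, "replacement")
  if (nchar(replacement) < 1L) stop("empty replacement", call. = FALSE)
  structure(list(kind = "point_mutation", contig = contig,
                 start = as.integer(start),
                 end = as.integer(start) + nchar(replacement) - 1L,
                 replacement = replacement), class = "edit_spec")
}

#' @rdname edit_spec
#' @export
edit_insertion <- function(contig, after, insert) {
  insert <- nuc(insert, "insert")
  if (nchar(insert) < 1L) stop("empty insert", call. = FALSE)
  structure(list(kind = "insertion", contig = contig,
                 after = as.integer(after), insert = insert),
            class = "edit_spec")
}

#' @rdname edit_spec
#' @export
edit_deletion <- function(contig, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (end < start) stop("deletion end before start", call. = FALSE)
  structure(list(kind = "deletion", contig = contig, start = start,
                 end = end), class = "edit_spec")
}

#' @rdname edit_spec
#' @export
edit_essential <- function(feature_id, residue, to_codon,
                           variant = c("own_promoter", "marker_promoter",
                                       "wt_restoring"),
                           rbs_boost = FALSE) {
  variant <- match.arg(variant)
  to_codon <- nuc(to_codon, "to_codon")
  if (nchar(to_codon) != 3L) stop("to_codon must be a codon", call. = FALSE)
  structure(list(kind = "essential_gene", feature_id = feature_id,
                 residue = as.integer(residue), to_codon = to_codon,
                 variant = variant, rbs_boost = isTRUE(rbs_boost)),
            class = "edit_spec")
}

#' @export
print.edit_spec <- function(x, ...) {
  cat("<edit_spec>", x$kind,
      switch(x$kind,
             point_mutation = sprintf("%s:%d-%d -> %s", x$contig, x$start,
                                      x$end, x$replacement),
             insertion = sprintf("%s: +%d bp after %d", x$contig,
                                 nchar(x$insert), x$after),
             deletion = sprintf("%s:%d-%d", x$contig, x$start, x$end),
             essential_gene = sprintf("%s codon %d -> %s (%s%s)",
                                      x$feature_id, x$residue, x$to_codon,
                                      x$variant,
                                      if (x$rbs_boost) ", rbs_boost" else "")),
      "\n")
  invisible(x)
}

edit_contig <- function(edit, genome) {
  if (edit$kind == "essential_gene") {
    feature_row(genome, edit$feature_id)$contig
  } else edit$contig
}

#' Apply an edit directly to a genome
#'
#' Produces the intended final genome for an [edit_spec]: the reference
#' against which the in-silico integrate/resolve round trip is compared.
#' Features overlapping the edited span are dropped; downstream features
#' shift with any length change.
#'
#' @param genome a [genome_record()].
#' @param edit an [edit_spec].
#' @return the edited [genome_record()].
#' @export
apply_edit <- function(genome, edit) {
  stopifnot(inherits(genome, "genome_record"), inherits(edit, "edit_spec"))
  switch(edit$kind,
    point_mutation = splice_contig(genome, edit$contig, edit$start,
                                   edit$end, edit$replacement),
    insertion = splice_contig(genome, edit$contig, edit$after + 1L,
                              edit$after, edit$insert),
    deletion = splice_contig(genome, edit$contig, edit$start, edit$end, ""),
    essential_gene = {
      f <- feature_row(genome, edit$feature_id)
      r <- edit$residue
      if (f$strand == "+") {
        gs <- f$start + 3L * (r - 1L)
        splice_contig(genome, f$contig, gs, gs + 2L, edit$to_codon)
      } else {
        ge <- f$end - 3L * (r - 1L)
        splice_contig(genome, f$contig, ge - 2L, ge, revcomp(edit$to_codon))
      }
    })
}

# Orient the design space so the edited feature reads on the plus strand.
# Returns the (possibly reverse-complemented) genome, the contig id and
# whether a flip happened; coordinates of features are remapped.
design_space <- function(genome, edit) {
  contig <- edit_contig(edit, genome)
  flipped <- FALSE
  if (edit$kind == "essential_gene") {
    f <- feature_row(genome, edit$feature_id)
    if (f$strand == "-") flipped <- TRUE
  }
  if (!flipped) {
    return(list(genome = genome, contig = contig, flipped = FALSE))
  }
  L <- nchar(genome$contigs[[contig]])
  contigs <- genome$contigs
  contigs[[contig]] <- revcomp(contigs[[contig]])
  fe <- genome$features
  on_c <- fe$contig == contig
  new_start <- L - fe$end[on_c] + 1L
  new_end <- L - fe$start[on_c] + 1L
  fe$start[on_c] <- new_start
  fe$end[on_c] <- new_end
  fe$strand[on_c] <- ifelse(fe$strand[on_c] == "+", "-", "+")
  g2 <- structure(list(contigs = contigs, features = fe),
                  class = "genome_record")
  list(genome = g2, contig = contig, flipped = TRUE)
}

# -- HR3 selection ----------------------------------------------------------

#' Choose the HR3 window for an edit
#'
#' HR3 is the 30-50 bp duplicated window that spans (or, in `after_hr3`
#' placements, immediately precedes) the desired modification. Point
#' mutations are centered (ties toward the 5' side); deletions get a
#' junction-fusion window; insertions are embedded when insert plus
#' minimal context fits within the maximum HR3 length and placed after
#' HR3 otherwise; essential-gene windows are snapped to codon boundaries,
#' and the wild-type-restoring variant uses a wild-type window ending
#' immediately before the edited codon.
#'
#' @param genome a [genome_record()].
#' @param edit an [edit_spec].
#' @param config a [design_config()].
#' @return list with `hr3` (edited window sequence, design-space
#'   orientation), `placement` (`inside_hr3`/`after_hr3`), `h1`, `h2`
#'   (the genomic span HR3 aligns to, design space) and `flipped`.
#' @export
choose_hr3 <- function(genome, edit, config = design_config()) {
  ds <- design_space(genome, edit)
  G <- ds$genome$contigs[[ds$contig]]
  n <- nchar(G)
  out <- switch(edit$kind,
    point_mutation = {
      span <- edit$end - edit$start + 1L
      L <- if (span <= config$hr3_len - 2L) config$hr3_len
           else if (span <= config$hr3_max - 2L) config$hr3_max
           else stop("design error: edited span (", span, " bp) wider than ",
                     "max HR3 minus context; consider an after_hr3 design",
                     call. = FALSE)
      left <- (L - span) %/% 2L
      h1 <- edit$start - left
      h2 <- h1 + L - 1L
      hr3 <- paste0(substr(G, h1, edit$start - 1L), edit$replacement,
                    substr(G, edit$end + 1L, h2))
      list(hr3 = hr3, placement = "inside_hr3", h1 = h1, h2 = h2)
    },
    deletion = {
      L <- config$hr3_len
      left <- (L + 1L) %/% 2L
      right <- L - left
      h1 <- edit$start - left
      h2 <- edit$end + right
      hr3 <- paste0(substr(G, h1, edit$start - 1L),
                    substr(G, edit$end + 1L, h2))
      list(hr3 = hr3, placement = "inside_hr3", h1 = h1, h2 = h2)
    },
    insertion = {
      j <- edit$after
      ins <- nchar(edit$insert)
      if (ins <= config$hr3_max - 2L * INSERTION_MIN_CTX) {
        L <- if (ins <= config$hr3_len - 2L * INSERTION_MIN_CTX)
          config$hr3_len else config$hr3_max
        ctx <- L - ins
        left <- ctx %/% 2L
        right <- ctx - left
        hr3 <- paste0(substr(G, j - left + 1L, j), edit$insert,
                      substr(G, j + 1L, j + right))
        list(hr3 = hr3, placement = "inside_hr3", h1 = j - left + 1L,
             h2 = j + right)
      } else {
        h1 <- j - config$hr3_len + 1L
        list(hr3 = substr(G, h1, j), placement = "after_hr3", h1 = h1,
             h2 = j)
      }
    },
    essential_gene = {
      f <- feature_row(ds$genome, edit$feature_id)
      if (f$kind != "CDS") stop("essential-gene target must be a CDS",
                                call. = FALSE)
      n_codons <- (f$end - f$start + 1L) %/% 3L
      n_cod <- max((config$hr3_min + 2L) %/% 3L, config$hr3_len %/% 3L)
      n_cod <- min(n_cod, config$hr3_max %/% 3L)
      if (3L * n_cod < config$hr3_min) n_cod <- n_cod + 1L
      r <- edit$residue
      if (r < 1L || r > n_codons) {
        stop("residue ", r, " outside CDS (", n_codons, " codons)",
             call. = FALSE)
      }
      if (edit$variant == "wt_restoring") {
        last_cod <- r - 1L
        first_cod <- last_cod - n_cod + 1L
        if (first_cod < 1L) {
          stop("design error: wt_restoring needs ", n_cod,
               " wild-type codons before the edited codon", call. = FALSE)
        }
        h1 <- f$start + 3L * (first_cod - 1L)
        h2 <- f$start + 3L * last_cod - 1L
        list(hr3 = substr(G, h1, h2), placement = "after_hr3", h1 = h1,
             h2 = h2)
      } else {
        left_c <- (n_cod - 1L) %/% 2L
        first_cod <- r - left_c
        lo_cod <- if (edit$variant == "marker_promoter") 2L else 1L
        first_cod <- max(lo_cod, min(first_cod, n_codons - n_cod + 1L))
        last_cod <- first_cod + n_cod - 1L
        if (last_cod > n_codons || r < first_cod || r > last_cod) {
          stop("design error: cannot fit a codon-aligned HR3 window ",
               "around residue ", r, call. = FALSE)
        }
        h1 <- f$start + 3L * (first_cod - 1L)
        h2 <- f$start + 3L * last_cod - 1L
        wt <- substr(G, h1, h2)
        off <- 3L * (r - first_cod)
        hr3 <- paste0(substr(wt, 1L, off), edit$to_codon,
                      substr(wt, off + 4L, nchar(wt)))
        list(hr3 = hr3, placement = "inside_hr3", h1 = h1, h2 = h2)
      }
    })
  if (out$h1 < 1L || out$h2 > n) {
    stop("design error: HR3 window runs off the contig", call. = FALSE)
  }
  if (nchar(out$hr3) < config$hr3_min || nchar(out$hr3) > config$hr3_max) {
    stop("design error: HR3 length ", nchar(out$hr3),
         " outside [", config$hr3_min, ", ", config$hr3_max, "]",
         call. = FALSE)
  }
  out$flipped <- ds$flipped
  out
}

# -- selection cassette -----------------------------------------------------

#' Build a selection cassette
#'
#' Element order: terminator block (0, 1 or 2 terminators with flanking
#' spacers), then the I-SceI recognition site, then the marker ORF. With
#' two terminators the block mirrors the published composition
#' spacer/terminator/spacer/terminator/spacer. An optional silent
#' RBS-boost of the marker 3' end (the `cat2` behavior) strengthens the
#' Shine-Dalgarno signal for a downstream translationally coupled ORF
#' without changing the marker protein.
#'
#' @param marker_name marker part name in `library`.
#' @param n_terminators 0, 1 or 2.
#' @param library an [element_library()].
#' @param rbs_boost_tail if `TRUE`, apply [silent_rbs_boost()] to the
#'   marker's last `rbs_tail_codons` codons.
#' @param model [rbs_model()] used for the boost.
#' @param rbs_tail_codons codons of marker tail exposed to the boost.
#' @return a `selection_cassette` with `segments` (ordered label/seq/role
#'   triples), `marker_name`, `n_terminators`, `boost` (the
#'   [silent_rbs_boost()] result or NULL).
#' @export
build_selection_cassette <- function(marker_name, n_terminators = 2L,
                                     library = default_element_library(),
                                     rbs_boost_tail = FALSE,
                                     model = rbs_model(),
                                     rbs_tail_codons = 8L) {
  stopifnot(inherits(library, "element_library"))
  n_terminators <- as.integer(n_terminators)
  if (!n_terminators %in% 0:2) stop("n_terminators must be 0, 1 or 2",
                                    call. = FALSE)
  marker <- lib_part(library, name = marker_name)
  if (marker$role != "marker") {
    stop("part '", marker_name, "' does not have role 'marker'",
         call. = FALSE)
  }
  seg <- function(label, part_obj) {
    list(label = label, seq = part_obj$seq, role = part_obj$role)
  }
  sp1 <- lib_part(library, "BBa_K259002")
  sp2 <- lib_part(library, "BBa_B0040")
  t1006 <- lib_part(library, "BBa_B1006")
  t1002 <- lib_part(library, "BBa_B1002")
  # the double-terminator block reuses the spacers at both ends; distinct
  # halves are taken (the published composition uses "part of" each
  # spacer) so no junction sequence recurs in the assembly
  half <- function(p, which) {
    n <- nchar(p$seq)
    s <- if (which == 1L) substr(p$seq, 1L, n %/% 2L)
         else substr(p$seq, n %/% 2L + 1L, n)
    list(label = "", seq = s, role = p$role)
  }
  lab <- function(x, label) { x$label <- label; x }
  segments <- list()
  if (n_terminators == 1L) {
    segments <- list(seg("SPACER_K259002", sp1), seg("TERM_B1006", t1006),
                     seg("SPACER_B0040", sp2))
  } else if (n_terminators == 2L) {
    segments <- list(lab(half(sp1, 1L), "SPACER_K259002a"),
                     lab(half(sp2, 1L), "SPACER_B0040a"),
                     seg("TERM_B1002", t1002),
                     lab(half(sp2, 2L), "SPACER_B0040b"),
                     seg("TERM_B1006", t1006),
                     lab(half(sp1, 2L), "SPACER_K259002b"))
  }
  boost <- NULL
  marker_seq <- marker$seq
  if (isTRUE(rbs_boost_tail)) {
    tl <- 3L * as.integer(rbs_tail_codons)
    stopifnot(tl < nchar(marker_seq))
    tail_seq <- substr(marker_seq, nchar(marker_seq) - tl + 1L,
                       nchar(marker_seq))
    boost <- silent_rbs_boost(tail_seq, library$table, model)
    marker_seq <- paste0(substr(marker_seq, 1L, nchar(marker_seq) - tl),
                         boost$modified_tail)
  }
  segments <- c(segments,
                list(list(label = "ISceI_site", seq = iscei_site(library),
                          role = "isceI_site"),
                     list(label = paste0("MARKER_", marker_name),
                          seq = marker_seq, role = "marker")))
  sc <- structure(list(segments = segments, marker_name = marker_name,
                       n_terminators = n_terminators, boost = boost),
                  class = "selection_cassette")
  check_orf(marker_seq, library$table,
            what = paste0("selection-cassette marker '", marker_name, "'"))
  site_pos <- which(vapply(segments, `[[`, "", "label") == "ISceI_site")
  stopifnot(length(site_pos) == 1L,
            n_terminators == 0L || site_pos > n_terminators)
  sc
}

selection_cassette_seq <- function(sc) {
  paste(vapply(sc$segments, `[[`, "", "seq"), collapse = "")
}

#' @export
print.selection_cassette <- function(x, ...) {
  cat("<selection_cassette>", x$n_terminators, "terminator(s), marker",
      x$marker_name, "-", nchar(selection_cassette_seq(x)), "bp",
      if (!is.null(x$boost)) "(RBS-boosted tail)" else "", "\n")
  invisible(x)
}
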