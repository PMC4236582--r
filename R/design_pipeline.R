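# The full design pipeline: edit spec -> mutation cassette + template
# fragments + design report.

# Reverse-complement a whole cassette (minus-strand targets are designed
# on the feature strand, then emitted in genome plus-strand orientation).
# Orientation-symmetric labels are swapped so that HR1 / HR3_copy1 / F5
# always name the 5'-most instances on the plus strand.
flip_segments <- function(segments) {
  swap <- c(HR1 = "HR2", HR2 = "HR1", HR3_copy1 = "HR3_copy2",
            HR3_copy2 = "HR3_copy1", F5 = "F3", F3 = "F5")
  rev(lapply(segments, function(s) {
    s$seq <- revcomp(s$seq)
    if (s$label %in% names(swap)) s$label <- swap[[s$label]]
    s
  }))
}

#' Full cassette sequence
#' @param cassette a `mutation_cassette`.
#' @return the ordered concatenation of all cassette segments.
#' @export
cassette_seq <- function(cassette) {
  stopifnot(inherits(cassette, "mutation_cassette"))
  paste(vapply(cassette$segments, `[[`, "", "seq"), collapse = "")
}

#' Cassette part annotations
#' @param cassette a `mutation_cassette`.
#' @return data.frame (`label`, `start`, `end`, `role`) tiling the
#'   cassette without gaps or overlaps.
#' @export
cassette_annotations <- function(cassette) {
  lens <- vapply(cassette$segments, function(s) nchar(s$seq), 0L)
  ends <- cumsum(lens)
  data.frame(label = vapply(cassette$segments, `[[`, "", "label"),
             start = ends - lens + 1L, end = ends,
             role = vapply(cassette$segments, `[[`, "", "role"),
             stringsAsFactors = FALSE)
}

#' Extract one cassette segment by label
#' @param cassette a `mutation_cassette`.
#' @param label segment label (e.g. `"HR1"`, `"HR3_copy1"`, `"RECODED"`).
#' @return the segment's nucleotide sequence.
#' @export
cassette_part_seq <- function(cassette, label) {
  for (s in cassette$segments) if (s$label == label) return(s$seq)
  stop("cassette has no segment labelled ", label, call. = FALSE)
}

#' @export
print.mutation_cassette <- function(x, ...) {
  ann <- cassette_annotations(x)
  cat("<mutation_cassette>", x$edit$kind,
      if (!is.null(x$edit$variant)) paste0("(", x$edit$variant, ")") else "",
      "-", nchar(cassette_seq(x)), "bp, HR3", nchar(x$hr3), "bp,",
      x$placement, "\n")
  for (i in seq_len(nrow(ann))) {
    cat(sprintf("  %-18s %6d..%-6d %s\n", ann$label[i], ann$start[i],
                ann$end[i], ann$role[i]))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Design a mutation cassette
#'
#' Builds the complete, validated design for an [edit_spec]: the mutation
#' cassette (HR1 / fragment5 / selection core / fragment3 / HR2 with the
#' HR3 duplication), template-plasmid assembly fragments, amplification
#' primers and a design report. Essential-gene designs recode the
#' ORF-restoring segment with [recode_synonymous()] (the library's I-SceI
#' site is a forbidden motif; the bundled E. coli codon-usage table
#' breaks ties) unless `recode = FALSE`, which reproduces the naive
#' non-recoded geometry for comparison.
#'
#' @param edit an [edit_spec].
#' @param genome a [genome_record()].
#' @param library an [element_library()].
#' @param config a [design_config()].
#' @param recode recode the ORF-restoring segment (default TRUE).
#' @return a `cassette_design` list: `cassette`, `template`
#'   (fragments + assembly plan), `primers`, `report` (see
#'   [validate_design()]).
#' @export
design_cassette <- function(edit, genome, library = default_element_library(),
                            config = design_config(), recode = TRUE) {
  stopifnot(inherits(edit, "edit_spec"), inherits(genome, "genome_record"),
            inherits(library, "element_library"),
            inherits(config, "design_config"))
  table <- library$table
  ds <- design_space(genome, edit)
  G <- ds$genome$contigs[[ds$contig]]
  hw <- choose_hr3(genome, edit, config)
  h1 <- hw$h1; h2 <- hw$h2; hr3 <- hw$hr3

  f5_ctx <- max(0L, config$frag_len - nchar(hr3))
  f3_ctx <- f5_ctx
  hr1_start <- h1 - f5_ctx - config$hr_len
  hr2_end <- h2 + f3_ctx + config$hr_len
  if (hr1_start < 1L || hr2_end > nchar(G)) {
    stop("design error: insufficient flanking sequence on the contig",
         call. = FALSE)
  }

  seg <- function(label, s, role = "target") {
    list(label = label, seq = s, role = role)
  }
  recode_opts <- recode_options(
    w_max = config$w_max, forbidden_motifs = iscei_site(library),
    codon_usage = ecoli_codon_usage())
  maybe_recode <- function(s) {
    if (!recode) {
      return(list(recoded = s, report = NULL, original = s))
    }
    r <- recode_synonymous(s, table, recode_opts)
    r$original <- s
    r
  }

  rbs_boost <- isTRUE(edit$rbs_boost) && edit$kind == "essential_gene" &&
    edit$variant == "marker_promoter"
  core <- build_selection_cassette(config$marker, config$n_terminators,
                                   library, rbs_boost_tail = rbs_boost,
                                   model = rbs_model(config$rbs_consensus,
                                                     config$rbs_spacer_min,
                                                     config$rbs_spacer_max))
  core_segs <- lapply(core$segments, function(s) {
    list(label = s$label, seq = s$seq, role = s$role)
  })

  pre <- list(seg("HR1", substr(G, hr1_start, h1 - f5_ctx - 1L), "hr"))
  if (f5_ctx > 0L) {
    pre <- c(pre, list(seg("F5", substr(G, h1 - f5_ctx, h1 - 1L))))
  }
  pre <- c(pre, list(seg("HR3_copy1", hr3, "hr3")))
  post <- list(seg("HR3_copy2", hr3, "hr3"))
  recode_res <- NULL
  mut_after <- NULL

  if (edit$kind == "essential_gene") {
    f <- feature_row(ds$genome, edit$feature_id)
    if (edit$variant %in% c("own_promoter", "wt_restoring")) {
      # restore the ORF (mutant for own_promoter, wild-type for
      # wt_restoring) upstream of the core so the gene's own promoter
      # drives it in the intermediate
      remainder <- substr(G, h2 + 1L, f$end)
      recode_res <- maybe_recode(remainder)
      pre <- c(pre, list(seg("RECODED", recode_res$recoded, "recoded")))
      if (edit$variant == "wt_restoring") {
        mut_after <- edit$to_codon  # the edit sits immediately after HR3
        post <- c(post, list(seg("MUTATION", edit$to_codon, "edit")))
        f3_start <- h2 + 4L
      } else {
        f3_start <- h2 + 1L
      }
    } else {  # marker_promoter: restored ORF reads out of the marker side
      head5 <- substr(G, f$start, h1 - 1L)
      if (nchar(head5) == 0L) {
        stop("design error: marker_promoter needs the HR3 window to start ",
             "after the start codon", call. = FALSE)
      }
      recode_res <- maybe_recode(head5)
      if (config$cat_orf_gap > 0L) {
        core_segs <- c(core_segs,
                       list(seg("ORF_GAP",
                                strrep("A", config$cat_orf_gap), "spacer")))
      }
      post <- c(list(seg("RECODED", recode_res$recoded, "recoded")), post)
      f3_start <- h2 + 1L
    }
  } else if (edit$kind == "insertion" && hw$placement == "after_hr3") {
    post <- c(post, list(seg("INSERT", edit$insert, "edit")))
    f3_start <- h2 + 1L
  } else {
    f3_start <- h2 + 1L
  }
  if (f3_ctx > 0L) {
    post <- c(post, list(seg("F3", substr(G, f3_start, h2 + f3_ctx))))
  }
  post <- c(post, list(seg("HR2", substr(G, h2 + f3_ctx + 1L, hr2_end),
                           "hr")))

  segments <- c(pre, core_segs, post)
  geometry <- list(hr1_start = hr1_start, h1 = h1, h2 = h2,
                   hr2_end = hr2_end, f5_ctx = f5_ctx, f3_ctx = f3_ctx,
                   f3_start = f3_start)
  integration <- integration_model_inputs(edit, segments, G, geometry,
                                          hw$placement)
  if (ds$flipped) segments <- flip_segments(segments)

  cassette <- structure(list(
    segments = segments,
    hr3 = if (ds$flipped) revcomp(hr3) else hr3,
    placement = hw$placement,
    edit = edit, core = core,
    target_contig = ds$contig,
    flipped = ds$flipped,
    config = config,
    geometry = geometry,
    integration = integration,
    recode = recode_res,
    recoded_flag = recode
  ), class = "mutation_cassette")

  template <- template_fragments(cassette, config)
  # an extreme-AT flank can defeat the Tm target; the design itself is
  # still valid, so a primer failure degrades to NULL (reported downstream)
  amp <- tryCatch(
    design_amplification_primers(
      cassette_seq(cassette),
      region(ds$contig, 1L, nchar(cassette_seq(cassette))), config,
      name_prefix = "M"),
    error = function(e) NULL)
  report <- validate_design(cassette, genome, library, config)
  structure(list(cassette = cassette, template = template, primers = amp,
                 report = report), class = "cassette_design")
}

#' @export
print.cassette_design <- function(x, ...) {
  print(x$cassette)
  print(x$report)
  invisible(x)
}

# Mask and mutation positions for the crossover-position model, built in
# design space before any strand flip. The modelled arm is the homology
# arm carrying the recoded/ORF-restoring segment (3' arm for
# marker_promoter and all non-essential kinds; mirrored 5' arm for
# own_promoter); wt_restoring models the 3' arm, whose edit sits
# immediately after HR3 copy 2.
integration_model_inputs <- function(edit, segments, G, geom, placement) {
  labels <- vapply(segments, `[[`, "", "label")
  seqs <- vapply(segments, `[[`, "", "seq")
  get <- function(lb) seqs[match(lb, labels)]
  cmp_mask <- function(donor, target) {
    stopifnot(nchar(donor) == nchar(target))
    strsplit(donor, "")[[1]] == strsplit(target, "")[[1]]
  }
  own_side <- edit$kind == "essential_gene" &&
    edit$variant %in% c("own_promoter")
  if (own_side) {
    # 5' arm: HR1 + F5 + HR3_copy1 + RECODED vs genomic window
    donor <- paste0(get("HR1"),
                    if ("F5" %in% labels) get("F5") else "",
                    get("HR3_copy1"), get("RECODED"))
    target_end <- geom$h2 + nchar(get("RECODED"))
    target <- substr(G, geom$hr1_start, target_end)
    m <- cmp_mask(donor, target)
    muts <- which(!m & seq_along(m) <=
                    (geom$h2 - geom$hr1_start + 1L) &
                  seq_along(m) > (geom$h1 - geom$hr1_start))
    # mirror so that "3' of the last mutation" means 5' of the first
    return(list(mask = rev(m), mutations = length(m) + 1L - muts,
                side = "five_prime"))
  }
  # 3' arm
  post_at <- match("HR3_copy2", labels)
  arm_labels <- labels[post_at:length(labels)]
  if ("RECODED" %in% labels && edit$kind == "essential_gene" &&
      edit$variant == "marker_promoter") {
    arm_labels <- c("RECODED", arm_labels)
  }
  donor_parts <- seqs[match(arm_labels, labels)]
  mask <- logical(0)
  muts <- integer(0)
  gpos <- if ("RECODED" %in% arm_labels) {
    geom$h1 - nchar(get("RECODED"))  # recoded aligns to CDS head
  } else geom$h1
  for (i in seq_along(arm_labels)) {
    lb <- arm_labels[i]
    dseq <- donor_parts[i]
    dn <- nchar(dseq)
    if (lb == "INSERT") {
      # inserted bases have no genomic counterpart
      mask <- c(mask, rep(FALSE, dn))
      muts <- c(muts, length(mask) - dn + seq_len(dn))
      next
    }
    if (edit$kind == "insertion" && placement == "inside_hr3" &&
        lb == "HR3_copy2") {
      # HR3 = left context + insert + right context; inserted bases have
      # no genomic counterpart and are masked false
      j <- edit$after
      left <- j - geom$h1 + 1L
      ins <- nchar(edit$insert)
      m <- c(cmp_mask(substr(dseq, 1L, left), substr(G, geom$h1, j)),
             rep(FALSE, ins),
             cmp_mask(substr(dseq, left + ins + 1L, dn),
                      substr(G, j + 1L, geom$h2)))
      mask <- c(mask, m)
      muts <- c(muts, length(mask) - dn + left + seq_len(ins))
      next
    }
    if (edit$kind == "deletion" && lb == "HR3_copy2") {
      left <- edit$start - geom$h1
      tgt <- paste0(substr(G, geom$h1, edit$start - 1L),
                    substr(G, edit$end + 1L, geom$h2))
      m <- cmp_mask(dseq, tgt)
      # pairing cannot span the fusion junction: mark the junction-
      # adjacent bases as the (non-transferable-past) edit
      m[c(left, left + 1L)] <- FALSE
      mask <- c(mask, m)
      muts <- c(muts, length(mask) - dn + c(left, left + 1L))
      next
    }
    tgt <- switch(lb,
      RECODED = substr(G, gpos, geom$h1 - 1L),
      HR3_copy2 = substr(G, geom$h1, geom$h2),
      MUTATION = substr(G, geom$h2 + 1L, geom$h2 + 3L),
      F3 = substr(G, geom$f3_start, geom$h2 + geom$f3_ctx),
      HR2 = substr(G, geom$h2 + geom$f3_ctx + 1L, geom$hr2_end),
      stop("unexpected arm segment ", lb))
    m <- cmp_mask(dseq, tgt)
    mask <- c(mask, m)
    if (lb %in% c("HR3_copy2", "MUTATION")) {
      d <- which(!m)
      muts <- c(muts, length(mask) - dn + d)
    }
  }
  list(mask = mask, mutations = muts, side = "three_prime")
}

#' Desired-integration probability of a design
#'
#' Applies [p_desired_integration()] to the design's modelled homology
#' arm (see the methods vignette for which arm is modelled per variant).
#'
#' @param cassette a `mutation_cassette`.
#' @param w minimal pairing window (bp); default from the design config.
#' @return probability in `[0, 1]`.
#' @export
design_p_desired <- function(cassette, w = NULL) {
  stopifnot(inherits(cassette, "mutation_cassette"))
  if (is.null(w)) w <- cassette$config$w_integration
  p_desired_integration(cassette$integration$mask,
                        cassette$integration$mutations, w)
}

# ---------------------------------------------------------------------------

#' Synthetic pUC19-style backbone stand-in
#'
#' A deterministic synthetic 300 bp linear backbone used for template-
#' plasmid assembly planning (labelled pHA-style). It is a synthetic
#' stand-in, not the real pUC19-derived fragment.
#'
#' @return nucleotide string.
#' @export
pha_backbone <- function() {
  with_seed(424242L, random_seq(300L, gc = 0.5))
}

# fragment5/fragment3 with vector/cassette overlaps and the assembly plan
template_fragments <- function(cassette, config = design_config()) {
  ann <- cassette_annotations(cassette)
  labels <- ann$label
  seqs <- vapply(cassette$segments, `[[`, "", "seq")
  core_roles <- c("spacer", "terminator", "isceI_site", "marker")
  core_idx <- which(ann$role %in% core_roles)
  stopifnot(length(core_idx) > 0L, all(diff(core_idx) == 1L))
  frag5 <- paste(seqs[seq_len(min(core_idx) - 1L)], collapse = "")
  core <- paste(seqs[core_idx], collapse = "")
  frag3 <- paste(seqs[seq(max(core_idx) + 1L, length(seqs))], collapse = "")
  ov <- config$overlap_len
  bb <- pha_backbone()
  f5w <- paste0(substr(bb, nchar(bb) - ov + 1L, nchar(bb)), frag5,
                substr(core, 1L, ov))
  f3w <- paste0(substr(core, nchar(core) - ov + 1L, nchar(core)), frag3,
                substr(bb, 1L, ov))
  plan <- plan_assembly(list(backbone = bb, fragment5 = f5w,
                             selection_cassette = core, fragment3 = f3w),
                        overlap_len = ov)
  list(fragment5_with_overlaps = f5w, fragment3_with_overlaps = f3w,
       backbone = "pHA_synthetic", overlap_len = ov, plan = plan)
}

# ---------------------------------------------------------------------------

#' Validate a design
#'
#' Runs every structural and model check and records pass/warn/fail per
#' check; never errors. Checks: HR1/HR2 uniqueness in the genome, single
#' I-SceI site in the cassette and absence from the untouched genome,
#' HR3 copy identity, HR3 and HR length bounds, marker ORF integrity,
#' recoded-fragment shared window <= w_max, hairpin screen on spacers,
#' desired-integration probability >= threshold, and the scarless
#' round-trip (resolve(integrate(genome)) equals the directly edited
#' genome).
#'
#' @param cassette a `mutation_cassette`.
#' @param genome the target [genome_record()].
#' @param library the [element_library()].
#' @param config a [design_config()].
#' @return a `design_report`: `checks` (data.frame name/status/detail),
#'   `p_desired`, `recode_report`, `rbs`, `provenance`.
#' @export
validate_design <- function(cassette, genome, library, config = cassette$config) {
  checks <- list()
  add <- function(name, status, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      name = name, status = status, detail = as.character(detail),
      stringsAsFactors = FALSE)
  }
  cseq <- cassette_seq(cassette)
  contig_seq <- genome$contigs[[cassette$target_contig]]

  hr1 <- cassette_part_seq(cassette, "HR1")
  hr2 <- cassette_part_seq(cassette, "HR2")
  n1 <- nrow(scan_motif(contig_seq, hr1))
  n2 <- nrow(scan_motif(contig_seq, hr2))
  add("hr1_unique", if (n1 == 1L) "pass" else "fail", paste0(n1, " hits"))
  add("hr2_unique", if (n2 == 1L) "pass" else "fail", paste0(n2, " hits"))

  site <- iscei_site(library)
  nc <- nrow(scan_motif(cseq, site, both_strands = TRUE))
  add("iscei_unique_in_cassette", if (nc == 1L) "pass" else "fail",
      paste0(nc, " sites"))
  ng <- sum(vapply(genome$contigs, function(s) {
    nrow(scan_motif(s, site, both_strands = TRUE))
  }, 0L))
  add("iscei_absent_from_genome", if (ng == 0L) "pass" else "warn",
      paste0(ng, " genomic sites"))

  copies <- vapply(cassette$segments, function(s) {
    if (s$label %in% c("HR3_copy1", "HR3_copy2")) s$seq else NA_character_
  }, "")
  copies <- copies[!is.na(copies)]
  add("hr3_copies_identical",
      if (length(copies) == 2L && copies[1] == copies[2]) "pass" else "fail")
  hl <- nchar(cassette$hr3)
  add("hr3_length",
      if (hl >= config$hr3_min && hl <= config$hr3_max) "pass" else "fail",
      paste0(hl, " bp"))
  add("hr_length",
      if (nchar(hr1) >= 100L) "pass"
      else if (nchar(hr1) >= 50L) "warn" else "fail",
      paste0(nchar(hr1), " bp (>= 100 recommended, >= 50 accepted)"))

  marker_seq <- NULL
  for (s in cassette$segments) if (s$role == "marker") marker_seq <- s$seq
  if (isTRUE(cassette$flipped)) marker_seq <- revcomp(marker_seq)
  mk <- tryCatch({
    check_orf(marker_seq, library$table); "pass"
  }, error = function(e) "fail")
  add("marker_orf_intact", mk)

  if (!is.null(cassette$recode) && !is.null(cassette$recode$report)) {
    wsh <- max_shared_window(cassette$recode$recoded,
                             cassette$recode$original)
    add("recoded_shared_window",
        if (wsh <= config$w_max) "pass" else "fail",
        paste0(wsh, " bp (w_max ", config$w_max, ")"))
  }

  hp_hits <- 0L
  for (s in cassette$segments) {
    if (s$role == "spacer") {
      hp_hits <- hp_hits + nrow(hairpin_screen(
        s$seq, config$hairpin_min_stem, config$hairpin_loop_min,
        config$hairpin_loop_max))
    }
  }
  add("spacer_hairpins", if (hp_hits == 0L) "pass" else "warn",
      paste0(hp_hits, " inverted repeat(s)"))

  p <- tryCatch(design_p_desired(cassette, config$w_integration),
                error = function(e) NA_real_)
  add("p_desired_integration",
      if (is.na(p)) "fail"
      else if (p >= config$p_threshold) "pass" else "warn",
      if (is.na(p)) "no eligible pairing window"
      else sprintf("%.3f (threshold %.2f)", p, config$p_threshold))

  rt <- tryCatch({
    final <- cleave_and_resolve(integrate_in_silico(genome, cassette),
                                cassette, library)
    want <- apply_edit(genome, cassette$edit)
    identical(final$contigs, want$contigs)
  }, error = function(e) FALSE)
  add("scarless_roundtrip", if (isTRUE(rt)) "pass" else "fail")

  structure(list(
    checks = do.call(rbind, checks),
    p_desired = p,
    recode_report = if (!is.null(cassette$recode)) cassette$recode$report,
    rbs = cassette$core$boost,
    provenance = list(config_hash = config_hash(config),
                      library_hash = rlang::hash(library),
                      edit = cassette$edit$kind)
  ), class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat("<design_report>\n")
  for (i in seq_len(nrow(x$checks))) {
    cat(sprintf("  [%s] %-26s %s\n", toupper(x$checks$status[i]),
                x$checks$name[i], x$checks$detail[i]))
  }
  invisible(x)
}
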