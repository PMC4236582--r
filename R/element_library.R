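# Element library: the reusable DNA parts a cassette is assembled from.
# Each part has a role; exactly one part per library carries role
# "isceI_site" and every marker part must contain one complete ORF.

PART_ROLES <- c("isceI_site", "terminator", "spacer", "marker", "promoter",
                "tag")

#' Construct an element-library part
#'
#' @param name part name (unique within a library).
#' @param seq nucleotide sequence.
#' @param role one of `isceI_site`, `terminator`, `spacer`, `marker`,
#'   `promoter`, `tag`.
#' @param notes free-text provenance note.
#' @return a `part` object.
#' @export
part <- function(name, seq, role, notes = "") {
  role <- match.arg(role, PART_ROLES)
  seq <- nuc(seq, paste0("part '", name, "'"))
  if (nchar(seq) == 0L) stop("part '", name, "' is empty", call. = FALSE)
  structure(list(name = name, seq = seq, role = role, notes = notes),
            class = "part")
}

#' Build an element library
#'
#' Validates the library invariants: unique names, exactly one I-SceI site
#' part, every marker part a complete ORF (initiation codon, terminal stop,
#' no internal stop) under `table`.
#'
#' @param parts list of [part()] objects.
#' @param table [codon_table()] used to check marker ORFs.
#' @return an `element_library` object (named list of parts).
#' @export
element_library <- function(parts, table = codon_table()) {
  stopifnot(length(parts) > 0L, all(vapply(parts, inherits, TRUE, "part")))
  nms <- vapply(parts, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop("duplicate part names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  names(parts) <- nms
  roles <- vapply(parts, `[[`, "", "role")
  if (sum(roles == "isceI_site") != 1L) {
    stop("library must contain exactly one part with role 'isceI_site' (",
         sum(roles == "isceI_site"), " found)", call. = FALSE)
  }
  for (p in parts[roles == "marker"]) {
    check_orf(p$seq, table,
              what = paste0("marker part '", p$name, "'"))
  }
  structure(list(parts = parts, table = table), class = "element_library")
}

check_orf <- function(seq, table, what = "ORF") {
  if (nchar(seq) %% 3L != 0L) {
    stop(what, " length not divisible by 3", call. = FALSE)
  }
  cods <- split_codons(seq)
  aa <- unname(table$code[cods])
  if (!(cods[1L] %in% table$starts)) {
    stop(what, " does not begin with an initiation codon", call. = FALSE)
  }
  if (aa[length(aa)] != "*") {
    stop(what, " does not end with a stop codon", call. = FALSE)
  }
  if (any(aa[-length(aa)] == "*")) {
    stop(what, " contains an internal stop codon", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.element_library <- function(x, ...) {
  roles <- vapply(x$parts, `[[`, "", "role")
  cat("<element_library>", length(x$parts), "parts\n")
  for (p in x$parts) {
    cat(sprintf("  %-14s %-10s %5d bp  %s\n", p$name, p$role,
                nchar(p$seq), p$notes))
  }
  invisible(x)
}

#' Look up library parts
#'
#' @param library an [element_library()].
#' @param role optional role filter.
#' @param name optional exact name.
#' @return a single `part` (by name) or list of parts (by role).
#' @export
lib_part <- function(library, name = NULL, role = NULL) {
  stopifnot(inherits(library, "element_library"))
  if (!is.null(name)) {
    p <- library$parts[[name]]
    if (is.null(p)) stop("no part named '", name, "' in library", call. = FALSE)
    return(p)
  }
  if (!is.null(role)) {
    role <- match.arg(role, PART_ROLES)
    return(Filter(function(p) p$role == role, library$parts))
  }
  library$parts
}

#' The library's I-SceI recognition site
#' @param library an [element_library()].
#' @return nucleotide string of the unique isceI_site part.
#' @export
iscei_site <- function(library) {
  lib_part(library, role = "isceI_site")[[1L]]$seq
}

# Deterministic synthetic ORF: initiation codon + random sense codons +
# stop, no internal stops. Used for placeholder marker/tag parts.
synthetic_orf <- function(n_codons, table, seed) {
  sense <- names(table$code)[table$code != "*" & table$code != "M"]
  with_seed(seed, {
    body <- sample(sense, n_codons - 2L, replace = TRUE)
    paste(c("ATG", body, "TAA"), collapse = "")
  })
}

#' Default element library
#'
#' Ships the canonical 18 bp I-SceI recognition site (TAGGGATAACAGGGTAAT;
#' an external-knowledge default, overridable via a library file) plus
#' deterministic synthetic placeholder sequences for the named terminator,
#' spacer, marker and tag parts. The iGEM part names (BBa_B1006, BBa_B1002,
#' BBa_K259002, BBa_B0040) mirror the published composition order, but the
#' public registry sequences are not bundled: the shipped sequences are
#' provisional stand-ins and real parts should be supplied via
#' [read_element_library()]. Terminator placeholders are strong synthetic
#' hairpin-plus-U-tract elements; marker ORFs (`cat`, `kan`, `dfrA`) are
#' synthetic complete ORFs of realistic length; `FLAG3x` encodes the
#' standard 3xFLAG peptide (DYKDHDGDYKDHDIDYKDDDDK) with a fixed codon
#' choice.
#'
#' @param table [codon_table()].
#' @return an [element_library()].
#' @export
default_element_library <- function(table = codon_table()) {
  hairpin_term <- function(stem_seed, stem_len = 9L) {
    stem <- with_seed(stem_seed, random_seq(stem_len, gc = 0.8))
    paste0(stem, "TTCG", revcomp(stem), "TTTTTTTT")
  }
  flag3x <- "GACTACAAAGACCATGACGGTGATTATAAAGATCATGACATCGATTACAAGGATGACGATGACAAG"
  parts <- list(
    part("ISceI", "TAGGGATAACAGGGTAAT", "isceI_site",
         "canonical 18 bp I-SceI recognition site (external-knowledge default)"),
    part("BBa_B1006", hairpin_term(101L), "terminator",
         "synthetic placeholder terminator (provisional; supply real part)"),
    part("BBa_B1002", hairpin_term(102L, 8L), "terminator",
         "synthetic placeholder terminator (provisional; supply real part)"),
    part("BBa_K259002", with_seed(103L, random_seq(30L, gc = 0.45)), "spacer",
         "synthetic placeholder spacer (provisional)"),
    part("BBa_B0040", with_seed(104L, random_seq(24L, gc = 0.45)), "spacer",
         "synthetic placeholder spacer (provisional)"),
    part("cat", synthetic_orf(220L, table, 105L), "marker",
         "synthetic placeholder chloramphenicol-resistance ORF (660 bp)"),
    part("kan", synthetic_orf(272L, table, 106L), "marker",
         "synthetic placeholder kanamycin-resistance ORF (816 bp)"),
    part("dfrA", synthetic_orf(165L, table, 107L), "marker",
         "synthetic placeholder trimethoprim-resistance ORF (495 bp)"),
    part("Pconst", with_seed(108L, random_seq(60L, gc = 0.4)), "promoter",
         "synthetic placeholder constitutive promoter"),
    part("FLAG3x", flag3x, "tag",
         "3xFLAG tag, standard peptide, fixed synthetic codon choice")
  )
  element_library(parts, table)
}

#' Read an element library from FASTA
#'
#' Multi-record FASTA whose headers carry whitespace-separated
#' `key=value` tags, e.g. `>cat role=marker name=cat notes=...`. A `name=`
#' tag overrides the leading identifier; `role=` is required.
#'
#' @param path FASTA file.
#' @param table [codon_table()].
#' @return an [element_library()].
#' @export
read_element_library <- function(path, table = codon_table()) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no records in ", path, call. = FALSE)
  parts <- lapply(seq_along(ss), function(i) {
    header <- names(ss)[i]
    toks <- strsplit(trimws(header), "\\s+")[[1]]
    kv <- toks[grepl("=", toks, fixed = TRUE)]
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    tags <- setNames(vals, keys)
    nm <- if ("name" %in% keys) tags[["name"]] else toks[1]
    if (!("role" %in% keys)) {
      stop("record '", nm, "' in ", path, " lacks a role= tag", call. = FALSE)
    }
    part(nm, as.character(ss[[i]]), tags[["role"]],
         notes = if ("notes" %in% keys) tags[["notes"]] else "")
  })
  element_library(parts, table)
}

#' Write an element library to FASTA
#'
#' @param library an [element_library()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_element_library <- function(library, path) {
  stopifnot(inherits(library, "element_library"))
  lines <- unlist(lapply(library$parts, function(p) {
    notes <- if (nzchar(p$notes)) paste0(" notes=", gsub("\\s+", "_", p$notes))
             else ""
    c(paste0(">", p$name, " role=", p$role, " name=", p$name, notes),
      wrap_seq(p$seq))
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

wrap_seq <- function(seq, width = 70L) {
  if (nchar(seq) == 0L) return(character(0))
  starts <- seq(1L, nchar(seq), width)
  substring(seq, starts, pmin(starts + width - 1L, nchar(seq)))
}
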