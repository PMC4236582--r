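# Readers and writers: GenBank flat files (minimal, local), FASTA +
# tab-separated feature tables, design bundles, edit specs as JSON.
# GenBank coordinates are 1-based inclusive, matching the internal
# convention, so no conversion is needed.

#' Read a genome
#'
#' @param path GenBank file, or FASTA file when `features_path` is given.
#' @param format `"genbank"` or `"fasta"`.
#' @param features_path tab-separated feature table for FASTA input
#'   (columns `feature_id`, `contig`, `start`, `end`, `strand`, `kind`,
#'   optional `product`; 1-based inclusive).
#' @param table [codon_table()] for CDS sanity checks.
#' @return a [genome_record()].
#' @export
read_genome <- function(path, format = c("genbank", "fasta"),
                        features_path = NULL, table = codon_table()) {
  format <- match.arg(format)
  if (format == "fasta") {
    ss <- Biostrings::readDNAStringSet(path)
    contigs <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
    features <- if (is.null(features_path)) empty_features() else {
      fe <- read.delim(features_path, stringsAsFactors = FALSE)
      if (!"product" %in% names(fe)) fe$product <- ""
      fe
    }
    return(genome_record(contigs, features, table))
  }
  read_genbank(path, table)
}

# -- minimal GenBank flat-file support --------------------------------------

read_genbank <- function(path, table = codon_table()) {
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(grepl("^LOCUS", lines)))
  recs <- recs[names(recs) != "0"]
  if (length(recs) == 0L) stop("no LOCUS records in ", path, call. = FALSE)
  contigs <- character(0)
  feats <- list()
  for (rec in recs) {
    locus <- strsplit(trimws(rec[1L]), "\\s+")[[1]][2]
    ori <- grep("^ORIGIN", rec)
    if (length(ori) != 1L) {
      stop("record ", locus, ": missing ORIGIN", call. = FALSE)
    }
    seq_lines <- rec[(ori + 1L):length(rec)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    contigs[locus] <- seq
    fstart <- grep("^FEATURES", rec)
    if (length(fstart) == 1L) {
      flines <- rec[(fstart + 1L):(ori - 1L)]
      feats[[locus]] <- parse_genbank_features(flines, locus)
    }
  }
  features <- do.call(rbind, c(list(empty_features()), unname(feats)))
  genome_record(contigs, features, table)
}

parse_genbank_features <- function(flines, contig) {
  # a new feature starts at column 6 with a key; qualifiers start with /
  is_key <- grepl("^ {5}\\S", flines)
  idx <- cumsum(is_key)
  out <- empty_features()
  n_auto <- 0L
  for (grp in split(flines[idx > 0L], idx[idx > 0L])) {
    head_toks <- strsplit(trimws(grp[1L]), "\\s+")[[1]]
    key <- head_toks[1L]
    loc <- paste(head_toks[-1L], collapse = "")
    if (key == "source") next
    strand <- "+"
    if (grepl("^complement\\(", loc)) {
      strand <- "-"
      loc <- sub("^complement\\(", "", sub("\\)$", "", loc))
    }
    m <- regmatches(loc, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", loc))[[1]]
    if (length(m) != 3L) {
      stop("unsupported location '", loc, "' in feature ", key,
           " (origin-spanning/join locations are not supported)",
           call. = FALSE)
    }
    quals <- grp[-1L]
    getq <- function(q) {
      hit <- grep(paste0("^\\s+/", q, "="), quals, value = TRUE)
      if (length(hit) == 0L) return(NA_character_)
      gsub('^[^=]*="?|"$', "", hit[1L])
    }
    n_auto <- n_auto + 1L
    fid <- getq("label")
    if (is.na(fid)) fid <- getq("locus_tag")
    if (is.na(fid)) fid <- paste0(key, "_", n_auto)
    kind <- if (key %in% c("CDS", "gene")) key else "misc"
    prod <- getq("product")
    out <- rbind(out, data.frame(
      feature_id = fid, contig = contig, start = as.integer(m[2L]),
      end = as.integer(m[3L]), strand = strand, kind = kind,
      product = if (is.na(prod)) "" else prod, stringsAsFactors = FALSE))
  }
  out
}

#' Write a genome as a GenBank flat file
#'
#' One LOCUS record per contig; features written with `label`, `product`
#' qualifiers and `complement()` locations for minus-strand features
#' (1-based inclusive coordinates). Circular/origin-spanning features are
#' not supported; maps are emitted linearized.
#'
#' @param genome a [genome_record()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  stopifnot(inherits(genome, "genome_record"))
  out <- character(0)
  for (nm in names(genome$contigs)) {
    seq <- genome$contigs[[nm]]
    out <- c(out, sprintf("LOCUS       %s %d bp    DNA     linear   UNA",
                          nm, nchar(seq)),
             sprintf("DEFINITION  %s.", nm),
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", nchar(seq)))
    fe <- genome$features[genome$features$contig == nm, , drop = FALSE]
    for (i in seq_len(nrow(fe))) {
      f <- fe[i, ]
      key <- if (f$kind == "misc") "misc_feature" else f$kind
      loc <- sprintf("%d..%d", f$start, f$end)
      if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
      out <- c(out, sprintf("     %-15s %s", key, loc),
               sprintf('                     /label="%s"', f$feature_id))
      if (nzchar(f$product)) {
        out <- c(out, sprintf('                     /product="%s"',
                              f$product))
      }
    }
    out <- c(out, "ORIGIN")
    low <- tolower(seq)
    pos <- seq(1L, nchar(low), 60L)
    for (p in pos) {
      chunk <- substr(low, p, min(p + 59L, nchar(low)))
      tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
      out <- c(out, sprintf("%9d %s", p, paste(tens, collapse = " ")))
    }
    out <- c(out, "//")
  }
  writeLines(out, path)
  invisible(path)
}

#' Write a genome as FASTA plus a feature table
#'
#' @param genome a [genome_record()].
#' @param fasta_path,features_path output files.
#' @return `fasta_path`, invisibly.
#' @export
write_genome_fasta <- function(genome, fasta_path, features_path = NULL) {
  stopifnot(inherits(genome, "genome_record"))
  lines <- unlist(lapply(names(genome$contigs), function(nm) {
    c(paste0(">", nm), wrap_seq(genome$contigs[[nm]]))
  }))
  writeLines(lines, fasta_path)
  if (!is.null(features_path)) {
    write.table(genome$features, features_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(fasta_path)
}

# -- edit specs as JSON -----------------------------------------------------

#' Read an edit spec from JSON
#'
#' The accepted document mirrors the [edit_spec] constructors: a `kind`
#' field plus the constructor's arguments (the shipped schema is in
#' `inst/schema/edit_spec.schema.json`).
#'
#' @param path JSON file.
#' @return an [edit_spec].
#' @export
read_edit_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$kind)) stop("edit spec lacks 'kind'", call. = FALSE)
  need <- function(...) {
    miss <- setdiff(c(...), names(x))
    if (length(miss)) {
      stop("edit spec (", x$kind, ") lacks field(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  switch(x$kind,
    point_mutation = {
      need("contig", "start", "replacement")
      edit_point_mutation(x$contig, x$start, x$replacement)
    },
    insertion = {
      need("contig", "after", "insert")
      edit_insertion(x$contig, x$after, x$insert)
    },
    deletion = {
      need("contig", "start", "end")
      edit_deletion(x$contig, x$start, x$end)
    },
    essential_gene = {
      need("feature_id", "residue", "to_codon", "variant")
      edit_essential(x$feature_id, x$residue, x$to_codon, x$variant,
                     rbs_boost = isTRUE(x$rbs_boost))
    },
    stop("unknown edit kind '", x$kind, "'", call. = FALSE))
}

#' Write a design bundle
#'
#' Emits the full machine-readable record of a design into `outdir`:
#' `cassette.gb` (annotated GenBank; the sequence equals the designed
#' cassette exactly and every cassette annotation appears as a feature),
#' `template_fragments.fasta`, `primers.tsv`, `report.json` and
#' `config.txt` (the configuration snapshot). Output is deterministic.
#'
#' @param design a `cassette_design` from [design_cassette()].
#' @param outdir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
write_design <- function(design, outdir) {
  stopifnot(inherits(design, "cassette_design"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cass <- design$cassette
  ann <- cassette_annotations(cass)
  gb_features <- data.frame(
    feature_id = ann$label, contig = "mutation_cassette",
    start = ann$start, end = ann$end, strand = "+",
    kind = ifelse(ann$role == "marker", "CDS", "misc"),
    product = ann$role, stringsAsFactors = FALSE)
  gb <- structure(list(
    contigs = c(mutation_cassette = cassette_seq(cass)),
    features = gb_features), class = "genome_record")
  files <- c(
    genbank = file.path(outdir, "cassette.gb"),
    fragments = file.path(outdir, "template_fragments.fasta"),
    primers = file.path(outdir, "primers.tsv"),
    report = file.path(outdir, "report.json"),
    config = file.path(outdir, "config.txt"))
  write_genbank(gb, files[["genbank"]])
  writeLines(c(">fragment5_with_overlaps",
               wrap_seq(design$template$fragment5_with_overlaps),
               ">fragment3_with_overlaps",
               wrap_seq(design$template$fragment3_with_overlaps)),
             files[["fragments"]])
  if (!is.null(design$primers)) {
    write_primer_tsv(design$primers, files[["primers"]],
                     purpose = "cassette amplification")
  } else {
    writeLines("name\tsequence\tlength\ttm\tpurpose", files[["primers"]])
  }
  rep <- design$report
  jsonlite::write_json(list(
    checks = rep$checks,
    p_desired = rep$p_desired,
    hr3 = cass$hr3,
    placement = cass$placement,
    annotations = ann,
    recode_report = rep$recode_report,
    provenance = rep$provenance
  ), files[["report"]], auto_unbox = TRUE, digits = NA, null = "null")
  write_config(cass$config, files[["config"]])
  files
}
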