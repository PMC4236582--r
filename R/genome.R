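# GenomeRecord: contigs (named nucleotide strings) + a feature table.
# Coordinates are 1-based inclusive on the plus strand throughout.

#' Genomic region
#'
#' @param contig contig identifier.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return a `region` object.
#' @export
region <- function(contig, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start) {
    stop("invalid region: start=", start, " end=", end, call. = FALSE)
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  structure(list(contig = contig, start = start, end = end, strand = strand),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region> %s:%d-%d(%s)\n", x$contig, x$start, x$end, x$strand))
  invisible(x)
}

region_width <- function(r) r$end - r$start + 1L

empty_features <- function() {
  data.frame(feature_id = character(0), contig = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             kind = character(0), product = character(0),
             stringsAsFactors = FALSE)
}

#' Construct a genome record
#'
#' Validates that every feature lies within its contig and that CDS
#' features have length divisible by 3, begin with an initiation codon and
#' end with a stop codon under `table` (violations warn, they do not
#' error, so partially annotated genomes remain usable).
#'
#' @param contigs named character vector (or list) of contig sequences.
#' @param features data.frame with columns `feature_id`, `contig`, `start`,
#'   `end`, `strand`, `kind` (`CDS`/`gene`/`misc`) and optionally `product`.
#' @param table [codon_table()] used for CDS sanity checks.
#' @return a `genome_record`.
#' @export
genome_record <- function(contigs, features = empty_features(),
                          table = codon_table()) {
  contigs <- vapply(contigs, nuc, "", what = "contig")
  if (is.null(names(contigs)) || any(!nzchar(names(contigs)))) {
    stop("contigs must be named", call. = FALSE)
  }
  if (anyDuplicated(names(contigs))) stop("duplicate contig ids", call. = FALSE)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(features) > 0L) {
    needed <- c("feature_id", "contig", "start", "end", "strand", "kind")
    miss <- setdiff(needed, names(features))
    if (length(miss)) {
      stop("feature table lacks columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    if (!"product" %in% names(features)) features$product <- ""
    features$start <- as.integer(features$start)
    features$end <- as.integer(features$end)
    for (i in seq_len(nrow(features))) {
      f <- features[i, ]
      if (!f$contig %in% names(contigs)) {
        stop("feature ", f$feature_id, " references unknown contig ",
             f$contig, call. = FALSE)
      }
      if (f$start < 1L || f$end > nchar(contigs[[f$contig]]) ||
          f$end < f$start) {
        stop("feature ", f$feature_id, " out of bounds: ", f$start, "-",
             f$end, " on ", f$contig, " (", nchar(contigs[[f$contig]]),
             " bp)", call. = FALSE)
      }
      if (!f$strand %in% c("+", "-")) {
        stop("feature ", f$feature_id, " has invalid strand", call. = FALSE)
      }
      if (!f$kind %in% c("CDS", "gene", "misc")) {
        stop("feature ", f$feature_id, " has invalid kind '", f$kind, "'",
             call. = FALSE)
      }
    }
    g <- structure(list(contigs = contigs, features = features),
                   class = "genome_record")
    for (i in which(features$kind == "CDS")) {
      f <- features[i, ]
      cds <- feature_seq(g, f$feature_id)
      if (nchar(cds) %% 3L != 0L) {
        warning("CDS ", f$feature_id, " length not divisible by 3",
                call. = FALSE)
        next
      }
      cods <- split_codons(cds)
      if (!(cods[1L] %in% table$starts)) {
        warning("CDS ", f$feature_id, " does not start with an initiation ",
                "codon", call. = FALSE)
      }
      if (table$code[[cods[length(cods)]]] != "*") {
        warning("CDS ", f$feature_id, " does not end with a stop codon",
                call. = FALSE)
      }
    }
    return(g)
  }
  structure(list(contigs = contigs, features = features),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record>", length(x$contigs), "contig(s),",
      nrow(x$features), "feature(s)\n")
  for (nm in names(x$contigs)) {
    cat("  ", nm, ": ", nchar(x$contigs[[nm]]), " bp\n", sep = "")
  }
  invisible(x)
}

#' Extract the sequence of a region
#'
#' Minus-strand regions return the reverse complement.
#'
#' @param genome a [genome_record()].
#' @param r a [region()].
#' @return nucleotide string on the requested strand.
#' @export
region_seq <- function(genome, r) {
  stopifnot(inherits(genome, "genome_record"), inherits(r, "region"))
  s <- genome$contigs[[r$contig]]
  if (is.null(s)) stop("unknown contig ", r$contig, call. = FALSE)
  if (r$end > nchar(s)) stop("region exceeds contig length", call. = FALSE)
  out <- substr(s, r$start, r$end)
  if (r$strand == "-") revcomp(out) else out
}

feature_row <- function(genome, feature_id) {
  i <- match(feature_id, genome$features$feature_id)
  if (is.na(i)) stop("no feature '", feature_id, "'", call. = FALSE)
  genome$features[i, ]
}

feature_region <- function(genome, feature_id) {
  f <- feature_row(genome, feature_id)
  region(f$contig, f$start, f$end, f$strand)
}

#' Extract a feature's sequence (on its own strand)
#' @param genome a [genome_record()].
#' @param feature_id feature identifier.
#' @return nucleotide string; for minus-strand CDS this is the coding strand.
#' @export
feature_seq <- function(genome, feature_id) {
  region_seq(genome, feature_region(genome, feature_id))
}

# Replace contig span [start, end] with `replacement`; features overlapping
# the span are dropped, downstream features are shifted. Cassette-derived
# annotations can be supplied as a feature table in replacement coordinates.
splice_contig <- function(genome, contig, start, end, replacement,
                          new_features = NULL) {
  s <- genome$contigs[[contig]]
  stopifnot(!is.null(s), start >= 1L, end <= nchar(s), end >= start - 1L)
  new_seq <- paste0(substr(s, 1L, start - 1L), replacement,
                    substr(s, end + 1L, nchar(s)))
  delta <- nchar(replacement) - (end - start + 1L)
  fe <- genome$features
  keep <- fe$contig != contig | fe$end < start | fe$start > end
  fe <- fe[keep, , drop = FALSE]
  later <- fe$contig == contig & fe$start > end
  fe$start[later] <- fe$start[later] + delta
  fe$end[later] <- fe$end[later] + delta
  if (!is.null(new_features) && nrow(new_features) > 0L) {
    nf <- new_features
    nf$contig <- contig
    nf$start <- nf$start + start - 1L
    nf$end <- nf$end + start - 1L
    fe <- rbind(fe, nf[, names(fe), drop = FALSE])
  }
  fe <- fe[order(fe$contig, fe$start), , drop = FALSE]
  rownames(fe) <- NULL
  contigs <- genome$contigs
  contigs[[contig]] <- new_seq
  structure(list(contigs = contigs, features = fe), class = "genome_record")
}
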