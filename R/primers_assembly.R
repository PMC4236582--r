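# Primer melting temperatures, amplification-primer design, and
# Gibson-style overlap assembly accounting.

# SantaLucia (1998) unified nearest-neighbor parameters:
# dH in kcal/mol, dS in cal/(mol K), 5'->3' dinucleotides.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
NN_INIT_DH <- c(G = 0.1, C = 0.1, A = 2.3, T = 2.3)
NN_INIT_DS <- c(G = -2.8, C = -2.8, A = 4.1, T = 4.1)

#' Primer melting temperature
#'
#' `wallace`: the rule-of-thumb 2(A+T) + 4(G+C) degC. `nn`: nearest-
#' neighbor thermodynamics (SantaLucia 1998 unified parameters) with a
#' 16.6 log10\[Na+\] salt correction, at the configured primer
#' concentration. `auto` (the default) uses wallace below 14 nt and nn
#' otherwise.
#'
#' @param seq primer sequence (>= 4 nt).
#' @param method `"auto"`, `"wallace"` or `"nn"`.
#' @param config a [design_config()] (supplies `tm_na_mM`,
#'   `tm_primer_nM`).
#' @return temperature in degC.
#' @export
tm <- function(seq, method = c("auto", "wallace", "nn"),
               config = design_config()) {
  seq <- nuc(seq, "primer")
  method <- match.arg(method)
  n <- nchar(seq)
  if (n < 4L) stop("primer shorter than 4 nt", call. = FALSE)
  if (method == "auto") method <- if (n < 14L) "wallace" else "nn"
  chars <- strsplit(seq, "")[[1]]
  if (method == "wallace") {
    at <- sum(chars %in% c("A", "T"))
    return(2 * at + 4 * (n - at))
  }
  pairs <- paste0(chars[-n], chars[-1L])
  dh <- NN_INIT_DH[[chars[1L]]] + NN_INIT_DH[[chars[n]]] + sum(NN_DH[pairs])
  ds <- NN_INIT_DS[[chars[1L]]] + NN_INIT_DS[[chars[n]]] + sum(NN_DS[pairs])
  conc <- config$tm_primer_nM * 1e-9
  t_kelvin <- dh * 1000 / (ds + 1.987 * log(conc / 4))
  t_kelvin - 273.15 + 16.6 * log10(config$tm_na_mM / 1000)
}

#' Design a forward/reverse amplification primer pair
#'
#' The forward primer starts at the region's first base; the reverse
#' primer is the reverse complement anchored at the region's last base.
#' Each anneal length grows from `primer_min_len` until the melting
#' temperature reaches `tm_target`; the pair is then balanced so that
#' their Tm difference is at most `tm_delta`.
#'
#' @param template template sequence.
#' @param r a [region()] within the template (the amplicon).
#' @param config a [design_config()].
#' @param name_prefix primer name prefix; the conventional `MF`/`MR`
#'   cassette-primer names are produced as `<prefix>F` / `<prefix>R`.
#' @return list of two `primer` objects (`forward`, `reverse`), each with
#'   `name`, `seq`, `anneal_len`, `tail_len`, `tm_anneal`, `binds`.
#' @export
design_amplification_primers <- function(template, r, config = design_config(),
                                         name_prefix = "M") {
  template <- nuc(template, "template")
  stopifnot(inherits(r, "region"))
  if (r$end > nchar(template)) stop("region outside template", call. = FALSE)
  grow <- function(anchor_seq) {
    # anchor_seq: template strand read 5'->3' from the priming end
    for (len in config$primer_min_len:config$primer_max_len) {
      if (len > nchar(anchor_seq)) break
      s <- substr(anchor_seq, 1L, len)
      if (tm(s, "auto", config) >= config$tm_target) return(s)
    }
    stop("primer error: cannot reach Tm ", config$tm_target,
         " degC within ", config$primer_max_len, " nt", call. = FALSE)
  }
  fwd_space <- substr(template, r$start, r$end)
  rev_space <- revcomp(fwd_space)
  fseq <- grow(fwd_space)
  rseq <- grow(rev_space)
  # balance the pair Tm difference by extending the cooler primer
  extend <- function(s, space) {
    if (nchar(s) >= min(config$primer_max_len, nchar(space))) return(NULL)
    substr(space, 1L, nchar(s) + 1L)
  }
  repeat {
    ft <- tm(fseq, "auto", config); rt <- tm(rseq, "auto", config)
    if (abs(ft - rt) <= config$tm_delta) break
    if (ft < rt) {
      nxt <- extend(fseq, fwd_space)
      if (is.null(nxt)) stop("primer error: cannot balance pair Tm within ",
                             config$tm_delta, " degC", call. = FALSE)
      fseq <- nxt
    } else {
      nxt <- extend(rseq, rev_space)
      if (is.null(nxt)) stop("primer error: cannot balance pair Tm within ",
                             config$tm_delta, " degC", call. = FALSE)
      rseq <- nxt
    }
  }
  mk <- function(name, s, bind_start, bind_end, strand) {
    structure(list(name = name, seq = s, anneal_len = nchar(s),
                   tail_len = 0L, tm_anneal = tm(s, "auto", config),
                   binds = region(r$contig %||% "template",
                                  bind_start, bind_end, strand)),
              class = "primer")
  }
  list(forward = mk(paste0(name_prefix, "F"), fseq,
                    r$start, r$start + nchar(fseq) - 1L, "+"),
       reverse = mk(paste0(name_prefix, "R"), rseq,
                    r$end - nchar(rseq) + 1L, r$end, "-"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total length of an overlap assembly
#'
#' Pure length arithmetic: the assembled product length is the sum of the
#' fragment lengths minus the sum of the junction overlaps that are
#' counted in both neighbors.
#'
#' @param fragment_lengths integer vector of fragment lengths (bp).
#' @param overlap_lengths junction overlap lengths; either a single value
#'   recycled to every junction or one value per junction
#'   (`length(fragment_lengths) - 1`). Zero-length junctions mean the
#'   printed segment lengths already partition the product.
#' @return total length in bp.
#' @export
assembly_total_length <- function(fragment_lengths, overlap_lengths = 0L) {
  fl <- as.integer(fragment_lengths)
  stopifnot(length(fl) >= 1L, all(fl >= 0L))
  nj <- length(fl) - 1L
  ol <- as.integer(overlap_lengths)
  if (length(ol) == 1L) ol <- rep(ol, nj)
  stopifnot(length(ol) == nj, all(ol >= 0L))
  sum(fl) - sum(ol)
}

#' Plan a Gibson-style overlap assembly
#'
#' Validates that each junction overlap (the last `overlap_len` bases of
#' fragment i) equals the first `overlap_len` bases of fragment i+1,
#' computes the exact product length and sequence, and flags junction
#' sequences that occur more than once across the assembly (mis-assembly
#' risk).
#'
#' @param fragments ordered list (optionally named) of fragment sequences;
#'   a `backbone` may simply be passed as the first fragment.
#' @param overlap_len junction overlap length, within 15-40 bp.
#' @return an `assembly_plan`: `fragments` (names, lengths), `junctions`
#'   (overlap sequences), `total_length`, `product` (assembled sequence),
#'   `ambiguous` (TRUE if any junction sequence is duplicated).
#' @export
plan_assembly <- function(fragments, overlap_len = 20L) {
  overlap_len <- as.integer(overlap_len)
  if (overlap_len < 15L || overlap_len > 40L) {
    stop("overlap_len must lie in [15, 40]", call. = FALSE)
  }
  frs <- vapply(fragments, nuc, "", what = "fragment")
  if (length(frs) < 2L) stop("need at least 2 fragments", call. = FALSE)
  if (is.null(names(frs)) || any(!nzchar(names(frs)))) {
    names(frs) <- paste0("fragment", seq_along(frs))
  }
  if (any(nchar(frs) < overlap_len)) {
    stop("every fragment must be at least overlap_len long", call. = FALSE)
  }
  nj <- length(frs) - 1L
  junctions <- character(nj)
  for (i in seq_len(nj)) {
    a <- frs[[i]]; b <- frs[[i + 1L]]
    suf <- substr(a, nchar(a) - overlap_len + 1L, nchar(a))
    pre <- substr(b, 1L, overlap_len)
    if (suf != pre) {
      stop("junction ", i, " mismatch between ", names(frs)[i], " and ",
           names(frs)[i + 1L], call. = FALSE)
    }
    junctions[i] <- suf
  }
  if (anyDuplicated(junctions)) {
    stop("ambiguity error: junction overlap sequence occurs more than once",
         call. = FALSE)
  }
  # an overlap recurring elsewhere in the assembly is a mis-assembly risk
  product <- frs[[1L]]
  for (i in 2L:length(frs)) {
    product <- paste0(product, substr(frs[[i]], overlap_len + 1L,
                                      nchar(frs[[i]])))
  }
  multi <- vapply(junctions, function(j) {
    nrow(scan_motif(product, j, both_strands = TRUE)) > 1L
  }, TRUE)
  plan <- structure(list(
    fragments = data.frame(name = names(frs), length = nchar(frs),
                           row.names = NULL, stringsAsFactors = FALSE),
    junctions = junctions,
    total_length = assembly_total_length(nchar(frs), overlap_len),
    product = product,
    ambiguous = any(multi)), class = "assembly_plan")
  stopifnot(nchar(plan$product) == plan$total_length)
  plan
}

#' @export
print.assembly_plan <- function(x, ...) {
  cat("<assembly_plan>", nrow(x$fragments), "fragments ->",
      x$total_length, "bp",
      if (x$ambiguous) "(AMBIGUOUS junctions)" else "", "\n")
  invisible(x)
}

#' Write primers as an ordering TSV
#'
#' @param primers list of `primer` objects.
#' @param path output TSV (name, sequence, length, tm, purpose).
#' @param purpose character vector recycled across primers.
#' @return `path`, invisibly.
#' @export
write_primer_tsv <- function(primers, path, purpose = "amplification") {
  df <- do.call(rbind, lapply(primers, function(p) {
    data.frame(name = p$name, sequence = p$seq, length = nchar(p$seq),
               tm = round(p$tm_anneal, 1), stringsAsFactors = FALSE)
  }))
  df$purpose <- rep(purpose, length.out = nrow(df))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
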