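#' @importFrom stats runif setNames
#' @importFrom utils modifyList read.delim write.table head tail
NULL

# Internal coordinate convention: 1-based, inclusive, plus strand --- the
# native R / IRanges / GenBank convention. All user-facing coordinates
# (reports, GenBank output, CLI) use the same convention, so no conversion
# layer is needed.

#' Normalize a nucleotide sequence
#'
#' Uppercases, converts RNA U to T and rejects any character outside ACGT.
#' Ambiguity codes (N, R, Y, ...) are rejected deliberately: a design tool
#' must not emit ambiguous synthesis orders.
#'
#' @param x character scalar (may be lowercase or contain U).
#' @param what label used in error messages.
#' @return uppercase ACGT string.
#' @export
nuc <- function(x, what = "sequence") {
  if (length(x) != 1L || !is.character(x) || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  s <- chartr("u", "T", toupper(x))
  s <- chartr("U", "T", s)
  if (nchar(s) > 0L && grepl("[^ACGT]", s)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", s), "")[[1]])
    stop(what, " contains non-ACGT characters (ambiguity codes are not ",
         "allowed): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  s
}

#' Reverse complement
#'
#' @param seq nucleotide string.
#' @return the reverse complement; `revcomp(revcomp(x)) == x`.
#' @export
revcomp <- function(seq) {
  seq <- nuc(seq)
  if (nchar(seq) == 0L) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Bacterial codon table
#'
#' Wraps a 64-entry codon to amino-acid map (stop rendered `*`) together
#' with the set of initiation codons. Default is the bacterial/archaeal
#' code (NCBI translation table 11).
#'
#' @param id NCBI genetic code id as a string, default `"11"`.
#' @return object of class `codon_table` with elements `code` (named
#'   character of length 64), `starts` (character vector of initiation
#'   codons) and `id`.
#' @export
codon_table <- function(id = "11") {
  code <- Biostrings::getGeneticCode(id, full.search = FALSE)
  # alt_init_codons lists alternative initiators; ATG always initiates
  starts <- unique(c("ATG", attr(code, "alt_init_codons")))
  stopifnot(length(code) == 64L, any(code == "*"))
  structure(list(code = code, starts = starts, id = id), class = "codon_table")
}

#' @export
print.codon_table <- function(x, ...) {
  cat("<codon_table> NCBI table", x$id, "-", sum(x$code == "*"),
      "stop codons; initiators:", paste(x$starts, collapse = " "), "\n")
  invisible(x)
}

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate an in-frame nucleotide sequence
#'
#' @param seq in-frame coding sequence (length divisible by 3).
#' @param table a [codon_table()].
#' @param require_start if `TRUE`, the first codon must be an initiation
#'   codon for `table` and is rendered as `M` (bacterial GTG/TTG starts).
#' @return amino-acid string; stops rendered as `*`.
#' @export
translate_cds <- function(seq, table = codon_table(), require_start = FALSE) {
  seq <- nuc(seq)
  if (nchar(seq) %% 3L != 0L) {
    stop("coding-frame error: length ", nchar(seq), " not divisible by 3",
         call. = FALSE)
  }
  if (nchar(seq) == 0L) return("")
  cods <- split_codons(seq)
  aa <- unname(table$code[cods])
  if (require_start) {
    if (!(cods[1L] %in% table$starts)) {
      stop("first codon ", cods[1L], " is not an initiation codon",
           call. = FALSE)
    }
    aa[1L] <- "M"
  }
  paste(aa, collapse = "")
}

#' Scan for exact motif occurrences
#'
#' Reports every exact occurrence (overlaps included) of `motif` in `seq`,
#' optionally on both strands. A minus-strand hit at position p means the
#' reverse complement of the motif starts at p on the plus strand.
#'
#' @param seq subject sequence.
#' @param motif query motif (non-empty).
#' @param both_strands search the reverse complement of the motif too.
#' @return data.frame with columns `pos` (1-based start on the plus strand)
#'   and `strand` (`"+"`/`"-"`), ordered by position.
#' @export
scan_motif <- function(seq, motif, both_strands = FALSE) {
  seq <- nuc(seq, "subject")
  motif <- nuc(motif, "motif")
  if (nchar(motif) == 0L) stop("motif must be non-empty", call. = FALSE)
  hits_one <- function(m) {
    if (nchar(seq) < nchar(m)) return(integer(0))
    Biostrings::start(Biostrings::matchPattern(m, Biostrings::DNAString(seq)))
  }
  plus_hits <- hits_one(motif)
  out <- data.frame(pos = plus_hits,
                    strand = rep("+", length(plus_hits)),
                    stringsAsFactors = FALSE)
  if (both_strands) {
    minus_hits <- hits_one(revcomp(motif))
    minus <- data.frame(pos = minus_hits,
                        strand = rep("-", length(minus_hits)),
                        stringsAsFactors = FALSE)
    # a palindromic motif hits both strands at the same position
    out <- rbind(out, minus)
  }
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Codon window in CDS coordinates
#'
#' Codon `n` occupies CDS bases `3n - 2 .. 3n` (1-based inclusive), the
#' convention used when reporting mutation positions in base pairs.
#'
#' @param residue_index codon/residue index, `>= 1` (vectorised).
#' @return matrix with columns `start` and `end`.
#' @export
codon_window <- function(residue_index) {
  if (length(residue_index) == 0L || any(is.na(residue_index)) ||
      any(residue_index < 1L) || any(residue_index != floor(residue_index))) {
    stop("residue_index must be integer(s) >= 1", call. = FALSE)
  }
  n <- as.integer(residue_index)
  cbind(start = 3L * n - 2L, end = 3L * n)
}

# substring extraction helper (1-based inclusive)
subseq_str <- function(seq, start, end) {
  if (end < start) return("")
  substr(seq, start, end)
}

# deterministic local RNG scope: runs `expr` under `seed` and restores the
# caller's RNG state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

#' Random nucleotide sequence
#'
#' Uniform (or GC-weighted) random ACGT string. Uses the current RNG
#' stream; wrap in `set.seed()` for reproducibility.
#'
#' @param n length in bp.
#' @param gc GC fraction, default 0.5.
#' @return character scalar.
#' @export
random_seq <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
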