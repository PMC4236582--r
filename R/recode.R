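# Synonymous-codon recoding: rewrite an in-frame fragment so that it
# encodes the same protein but shares no exact window longer than w_max
# with the original, destroying its capacity for homologous recombination
# with the genomic copy.

#' Recoding options
#'
#' @param w_max maximum exact window (bp) the recoded sequence may share
#'   with the original; must be >= 3 (below one codon is meaningless).
#' @param forbidden_motifs character vector of motifs that must not appear
#'   in the recoded output (screened on both strands).
#' @param objective currently only `"max_hamming"`: per-codon maximal
#'   nucleotide Hamming distance from the original codon.
#' @param codon_usage optional named numeric codon -> relative frequency
#'   map; when supplied it is the first tie-break among equally distant
#'   synonyms (higher frequency wins), ahead of lexicographic order.
#' @return a `recode_options` object.
#' @export
recode_options <- function(w_max = 14L, forbidden_motifs = character(0),
                           objective = "max_hamming", codon_usage = NULL) {
  objective <- match.arg(objective, "max_hamming")
  w_max <- as.integer(w_max)
  if (is.na(w_max) || w_max < 3L) stop("w_max must be >= 3", call. = FALSE)
  forbidden_motifs <- vapply(forbidden_motifs, nuc, "", what = "forbidden motif")
  if (any(nchar(forbidden_motifs) == 0L)) {
    stop("forbidden motifs must be non-empty", call. = FALSE)
  }
  if (!is.null(codon_usage)) {
    stopifnot(is.numeric(codon_usage), !is.null(names(codon_usage)))
  }
  structure(list(w_max = w_max, forbidden_motifs = unname(forbidden_motifs),
                 objective = objective, codon_usage = codon_usage),
            class = "recode_options")
}

#' Approximate E. coli K-12 codon usage (per 1000 codons)
#'
#' Standard reference relative-usage values, bundled as a tie-break
#' preference table for [recode_synonymous()]. Only the ordering within a
#' synonym family matters for recoding.
#'
#' @return named numeric vector of length 64.
#' @export
ecoli_codon_usage <- function() {
  c(TTT = 22.1, TTC = 16.6, TTA = 13.9, TTG = 13.0,
    CTT = 11.2, CTC = 10.5, CTA = 3.9, CTG = 52.6,
    ATT = 30.5, ATC = 25.1, ATA = 4.4, ATG = 27.9,
    GTT = 18.3, GTC = 15.3, GTA = 10.9, GTG = 26.4,
    TCT = 8.5, TCC = 8.6, TCA = 7.2, TCG = 8.9,
    CCT = 7.0, CCC = 5.5, CCA = 8.4, CCG = 23.2,
    ACT = 9.0, ACC = 23.4, ACA = 7.1, ACG = 14.4,
    GCT = 15.3, GCC = 25.5, GCA = 20.1, GCG = 33.6,
    TAT = 16.2, TAC = 12.2, TAA = 2.0, TAG = 0.2,
    CAT = 12.9, CAC = 9.7, CAA = 15.3, CAG = 28.8,
    AAT = 17.7, AAC = 21.7, AAA = 33.6, AAG = 10.3,
    GAT = 32.1, GAC = 19.1, GAA = 39.4, GAG = 17.8,
    TGT = 5.2, TGC = 6.4, TGA = 1.0, TGG = 15.2,
    CGT = 20.9, CGC = 22.0, CGA = 3.6, CGG = 5.4,
    AGT = 8.8, AGC = 16.1, AGA = 2.1, AGG = 1.2,
    GGT = 24.7, GGC = 29.6, GGA = 8.0, GGG = 11.1)
}

codon_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# synonyms of `codon` under `table` (including itself)
synonyms <- function(codon, table) {
  names(table$code)[table$code == table$code[[codon]]]
}

# candidates for one codon, best first: exclude the original when the
# family is degenerate; rank by Hamming distance desc, then usage desc,
# then lexicographic asc
ranked_candidates <- function(codon, table, usage = NULL) {
  syn <- synonyms(codon, table)
  if (length(syn) == 1L) return(syn)
  cand <- setdiff(syn, codon)
  h <- vapply(cand, codon_hamming, 0, b = codon)
  u <- if (is.null(usage)) rep(0, length(cand)) else {
    v <- usage[cand]; v[is.na(v)] <- 0; unname(v)
  }
  cand[order(-h, -u, cand)]
}

#' Longest exact window shared by two sequences
#'
#' Length of the longest common substring (same strand), the quantity the
#' recoder is constrained to keep at or below `w_max`.
#'
#' @param a,b nucleotide strings.
#' @return integer length (0 if nothing is shared).
#' @export
max_shared_window <- function(a, b) {
  a <- nuc(a); b <- nuc(b)
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L || nb == 0L) return(0L)
  kmers <- function(s, k) {
    n <- nchar(s)
    unique(substring(s, 1:(n - k + 1L), k:n))
  }
  shares <- function(k) any(kmers(a, k) %in% kmers(b, k))
  hi <- min(na, nb)
  if (!shares(1L)) return(0L)
  lo <- 1L
  # largest k with a shared k-mer; shares() is monotone non-increasing in k
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (shares(mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

# locate one occurrence of a shared window of length k: returns c(start_a)
# or NA if none
shared_window_at <- function(a, b, k) {
  na <- nchar(a)
  if (k > na || k > nchar(b)) return(NA_integer_)
  ka <- substring(a, 1:(na - k + 1L), k:na)
  hit <- which(ka %in% substring(b, 1:(nchar(b) - k + 1L), k:nchar(b)))
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Synonymously recode an in-frame fragment
#'
#' Replaces every codon whose amino acid has more than one codon with a
#' different synonymous codon, maximizing per-codon nucleotide Hamming
#' distance (ties broken by codon-usage frequency when supplied, then
#' lexicographic order). Constraint repair then rechooses codons, scanning
#' left to right, until the output contains no forbidden motif and shares
#' no exact window longer than `opts$w_max` with the original.
#'
#' @param cds_fragment in-frame fragment; no internal stop codons (a
#'   terminal stop is allowed and is recoded to a synonymous stop).
#' @param table a [codon_table()].
#' @param opts a [recode_options()].
#' @return list with `recoded` (nucleotide string) and `report` (one row
#'   per codon: index, aa, from, to, changed, degenerate, deviation; a
#'   deviation marks a codon moved off the top-ranked choice by
#'   constraint repair).
#' @export
recode_synonymous <- function(cds_fragment, table = codon_table(),
                              opts = recode_options()) {
  seq <- nuc(cds_fragment)
  if (nchar(seq) %% 3L != 0L) {
    stop("fragment length not divisible by 3", call. = FALSE)
  }
  cods <- split_codons(seq)
  nc <- length(cods)
  if (nc == 0L) {
    return(list(recoded = "", report = data.frame(
      index = integer(0), aa = character(0), from = character(0),
      to = character(0), changed = logical(0), degenerate = logical(0),
      deviation = logical(0), stringsAsFactors = FALSE)))
  }
  aa <- unname(table$code[cods])
  if (any(aa[-nc] == "*")) {
    stop("fragment contains an internal stop codon at codon ",
         which(aa[-nc] == "*")[1L], call. = FALSE)
  }
  cand <- lapply(cods, ranked_candidates, table = table,
                 usage = opts$codon_usage)
  pick <- vapply(cand, `[[`, "", 1L)

  current <- function(p) paste(p, collapse = "")
  violation <- function(p) {
    s <- current(p)
    for (m in opts$forbidden_motifs) {
      hits <- scan_motif(s, m, both_strands = TRUE)
      if (nrow(hits) > 0L) {
        return(list(kind = "motif", start = hits$pos[1L],
                    end = hits$pos[1L] + nchar(m) - 1L, motif = m))
      }
    }
    k <- opts$w_max + 1L
    at <- shared_window_at(s, seq, k)
    if (!is.na(at)) {
      return(list(kind = "window", start = at, end = at + k - 1L))
    }
    NULL
  }

  max_iter <- 50L * nc + 50L
  iter <- 0L
  repeat {
    v <- violation(pick)
    if (is.null(v)) break
    iter <- iter + 1L
    if (iter > max_iter) {
      stop("recoding infeasible: constraint repair did not converge near ",
           "bases ", v$start, "-", v$end, call. = FALSE)
    }
    first_cod <- (v$start - 1L) %/% 3L + 1L
    last_cod <- (v$end - 1L) %/% 3L + 1L
    span_cods <- first_cod:min(last_cod, nc)
    improved <- FALSE
    for (ci in span_cods) {
      alts <- setdiff(cand[[ci]], pick[ci])
      for (alt in alts) {
        trial <- pick
        trial[ci] <- alt
        tv <- violation(trial)
        better <- is.null(tv) ||
          (tv$start > v$start) ||  # this violation cleared; scan moves right
          (tv$kind == "window" && v$kind == "motif")
        if (better) {
          pick <- trial
          improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) {
      stop("recoding infeasible: no synonymous choice removes the ",
           if (v$kind == "motif") paste0("forbidden motif ", v$motif)
           else paste0("shared window (> ", opts$w_max, " bp)"),
           " spanning recoded bases ", v$start, "-", v$end,
           " (codons ", first_cod, "-", min(last_cod, nc), ")",
           call. = FALSE)
    }
  }

  recoded <- current(pick)
  degen <- vapply(cods, function(cd) length(synonyms(cd, table)) > 1L, TRUE)
  top <- vapply(cand, `[[`, "", 1L)
  report <- data.frame(
    index = seq_len(nc), aa = aa, from = cods, to = pick,
    changed = pick != cods, degenerate = degen,
    deviation = pick != top, stringsAsFactors = FALSE)
  rownames(report) <- NULL
  stopifnot(translate_cds(recoded, table) == translate_cds(seq, table))
  list(recoded = recoded, report = report)
}

#' Shine-Dalgarno model
#'
#' @param consensus consensus ribosome-binding sequence (>= 4 nt), default
#'   `AGGAGG`.
#' @param spacer_min,spacer_max allowed spacer (nt between the consensus
#'   3' end and the downstream start codon), default 4-13.
#' @return an `rbs_model` object.
#' @export
rbs_model <- function(consensus = "AGGAGG", spacer_min = 4L,
                      spacer_max = 13L) {
  consensus <- nuc(consensus, "consensus")
  spacer_min <- as.integer(spacer_min); spacer_max <- as.integer(spacer_max)
  stopifnot(nchar(consensus) >= 4L, spacer_min > 0L,
            spacer_min <= spacer_max)
  structure(list(consensus = consensus, spacer_min = spacer_min,
                 spacer_max = spacer_max), class = "rbs_model")
}

# matches of the consensus placed so its 3' end sits `spacer` nt before
# the end of `window`; positions hanging off the 5' end score nothing
placement_matches <- function(window, model, spacer) {
  W <- nchar(window)
  L <- nchar(model$consensus)
  cons_end <- W - spacer
  cons_start <- cons_end - L + 1L
  if (cons_end < 1L) return(NA_integer_)     # consensus entirely off-window
  lo <- max(1L, cons_start)
  wchars <- substring(window, lo, cons_end)
  cchars <- substring(model$consensus, lo - cons_start + 1L, L)
  sum(strsplit(wchars, "")[[1]] == strsplit(cchars, "")[[1]])
}

#' Score a ribosome-binding-site window
#'
#' `window` is the sequence ending immediately before a start codon. The
#' score is the maximum number of consensus-matching positions over all
#' placements whose spacer (consensus 3' end to start codon) lies within
#' the model's spacer range; ties resolve to the smallest spacer. Windows
#' too short for a full placement are scored over the available
#' placements only.
#'
#' @param window upstream sequence (plus strand, ends at start codon - 1).
#' @param model an [rbs_model()].
#' @return list with `score`, `spacer` (NA if no placement fits) and
#'   `start` (1-based consensus start within the window; may be < 1 when
#'   the consensus overhangs the window 5' end).
#' @export
rbs_score <- function(window, model = rbs_model()) {
  window <- nuc(window, "window")
  best <- list(score = 0L, spacer = NA_integer_, start = NA_integer_)
  for (sp in model$spacer_min:model$spacer_max) {
    m <- placement_matches(window, model, sp)
    if (is.na(m)) next
    if (is.na(best$spacer) || m > best$score) {
      best <- list(score = as.integer(m), spacer = sp,
                   start = nchar(window) - sp - nchar(model$consensus) + 1L)
    }
  }
  best
}

#' Silently boost a ribosome-binding site within a CDS tail
#'
#' Given the in-frame 3' tail of an upstream CDS that immediately precedes
#' a downstream start codon, introduces silent (synonymous) mutations that
#' maximize the Shine-Dalgarno consensus score of the tail. Because, for a
#' fixed consensus placement, each codon overlapping the consensus can be
#' optimized independently, an exact optimum over all fully-silent
#' variants is found by scanning placements.
#'
#' @param upstream_cds_tail in-frame tail (length divisible by 3); may end
#'   with the upstream gene's stop codon.
#' @param table a [codon_table()].
#' @param model an [rbs_model()].
#' @return list with `modified_tail`, `mutations` (data.frame pos, from,
#'   to), `score_before`, `score_after` (the maximum achievable over all
#'   silent variants; never less than `score_before`).
#' @export
silent_rbs_boost <- function(upstream_cds_tail, table = codon_table(),
                             model = rbs_model()) {
  tail0 <- nuc(upstream_cds_tail, "tail")
  if (nchar(tail0) %% 3L != 0L) {
    stop("tail length not divisible by 3", call. = FALSE)
  }
  before <- rbs_score(tail0, model)
  cods <- split_codons(tail0)
  nc <- length(cods)
  W <- nchar(tail0)
  L <- nchar(model$consensus)
  cons <- strsplit(model$consensus, "")[[1]]

  best <- list(score = -1L, spacer = NA_integer_, cods = cods)
  for (sp in model$spacer_min:model$spacer_max) {
    cons_end <- W - sp
    if (cons_end < 1L) next
    cons_start <- cons_end - L + 1L
    trial <- cods
    total <- 0L
    for (ci in seq_len(nc)) {
      c_lo <- 3L * ci - 2L
      c_hi <- 3L * ci
      lo <- max(c_lo, max(1L, cons_start))
      hi <- min(c_hi, cons_end)
      if (lo > hi) next
      offs <- lo:hi                       # tail positions under the consensus
      within <- offs - c_lo + 1L          # 1..3 within the codon
      target <- cons[offs - cons_start + 1L]
      syn <- synonyms(cods[ci], table)
      m <- vapply(syn, function(s) {
        sum(strsplit(s, "")[[1]][within] == target)
      }, 0L)
      mx <- max(m)
      winners <- syn[m == mx]
      # prefer keeping the original codon, else lexicographic
      choice <- if (cods[ci] %in% winners) cods[ci] else sort(winners)[1L]
      trial[ci] <- choice
      total <- total + mx
    }
    if (total > best$score) {
      best <- list(score = total, spacer = sp, cods = trial)
    }
  }

  modified <- paste(best$cods, collapse = "")
  after <- rbs_score(modified, model)
  o <- strsplit(tail0, "")[[1]]; mnew <- strsplit(modified, "")[[1]]
  diffs <- which(o != mnew)
  mutations <- data.frame(pos = diffs, from = o[diffs], to = mnew[diffs],
                          stringsAsFactors = FALSE)
  stopifnot(translate_cds(modified, table) == translate_cds(tail0, table),
            after$score >= before$score)
  list(modified_tail = modified, mutations = mutations,
       score_before = before$score, score_after = after$score)
}

#' Screen for hairpin-forming inverted repeats
#'
#' Reports all maximal inverted repeats (stem of perfect reverse-
#' complementarity separated by a short loop), a light-weight surrogate
#' for thermodynamic secondary-structure prediction. A hit is maximal when
#' its stem cannot be extended outward, nor inward without shrinking the
#' loop below `loop_min`.
#'
#' @param seq nucleotide string.
#' @param min_stem minimum stem length (>= 3).
#' @param loop_min,loop_max allowed loop lengths (nt).
#' @return data.frame with `stem_len`, `pos5` (1-based start of the 5'
#'   arm), `pos3` (start of the 3' arm) and `loop_len`.
#' @export
hairpin_screen <- function(seq, min_stem = 8L, loop_min = 3L,
                           loop_max = 10L) {
  seq <- nuc(seq)
  min_stem <- as.integer(min_stem)
  if (min_stem < 3L) stop("min_stem must be >= 3", call. = FALSE)
  stopifnot(loop_min >= 0L, loop_min <= loop_max)
  n <- nchar(seq)
  out <- data.frame(stem_len = integer(0), pos5 = integer(0),
                    pos3 = integer(0), loop_len = integer(0))
  if (n < 2L * min_stem + loop_min) return(out)
  s <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  is_pair <- function(i, j) comp[[s[i]]] == s[j]
  for (L in loop_min:loop_max) {
    for (i in seq_len(n)) {            # i = 3' end of the 5' arm
      j <- i + L + 1L                  # j = 5' start of the 3' arm
      if (j > n) break
      if (!is_pair(i, j)) next
      # inward-maximality: subsumed by the loop L-2 hit at the same center
      if (L - 2L >= loop_min && i + 1L <= n && j - 1L >= 1L &&
          i + 1L < j - 1L && is_pair(i + 1L, j - 1L)) next
      k <- 1L
      while (i - k >= 1L && j + k <= n && is_pair(i - k, j + k)) k <- k + 1L
      if (k >= min_stem) {
        out <- rbind(out, data.frame(stem_len = k, pos5 = i - k + 1L,
                                     pos3 = j, loop_len = L))
      }
    }
  }
  out <- out[order(out$pos5, out$pos3), , drop = FALSE]
  rownames(out) <- NULL
  out
}
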