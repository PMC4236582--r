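# Independent brute-force oracles. These deliberately use different
# algorithms from the package implementations they check.

# O(n*m) sliding-window motif scan
oracle_scan <- function(seq, motif, both_strands = FALSE) {
  n <- nchar(seq); m <- nchar(motif)
  hit <- function(pat) {
    if (n < m) return(integer(0))
    which(vapply(seq_len(n - m + 1L),
                 function(i) substr(seq, i, i + m - 1L) == pat, TRUE))
  }
  plus <- hit(motif)
  out <- data.frame(pos = plus, strand = rep("+", length(plus)),
                    stringsAsFactors = FALSE)
  if (both_strands) {
    minus <- hit(revcomp(motif))
    out <- rbind(out, data.frame(pos = minus,
                                 strand = rep("-", length(minus)),
                                 stringsAsFactors = FALSE))
  }
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# longest common substring by explicit diagonal-shift run scanning
oracle_lcs <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  if (na == 0L || nb == 0L) return(0L)
  best <- 0L
  for (shift in (-(nb - 1L)):(na - 1L)) {
    ia <- max(1L, 1L + shift):min(na, nb + shift)
    ib <- ia - shift
    eq <- ca[ia] == cb[ib]
    r <- rle(eq)
    runs <- r$lengths[r$values]
    if (length(runs)) best <- max(best, max(runs))
  }
  as.integer(best)
}

# exhaustive enumeration of synonymous recodings maximizing total Hamming
# distance, tie-broken per codon by usage (desc) then lexicographic (asc);
# degenerate codons must differ from the original
oracle_recode <- function(fragment, table, usage = NULL) {
  cods <- substring(fragment, seq(1, nchar(fragment), 3),
                    seq(3, nchar(fragment), 3))
  fams <- lapply(cods, function(cd) {
    syn <- names(table$code)[table$code == table$code[[cd]]]
    if (length(syn) > 1L) setdiff(syn, cd) else syn
  })
  combos <- expand.grid(fams, stringsAsFactors = FALSE)
  ham <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  tot <- apply(combos, 1L, function(row) {
    sum(mapply(ham, unlist(row), cods))
  })
  keep <- combos[tot == max(tot), , drop = FALSE]
  for (j in seq_along(cods)) {
    if (nrow(keep) == 1L) break
    if (!is.null(usage)) {
      u <- usage[keep[[j]]]; u[is.na(u)] <- 0
      keep <- keep[u == max(u), , drop = FALSE]
    }
    if (nrow(keep) > 1L) {
      keep <- keep[keep[[j]] == min(keep[[j]]), , drop = FALSE]
    }
  }
  paste(unlist(keep[1L, ]), collapse = "")
}

# independent RBS score: explicit per-spacer, per-position loop
oracle_rbs_score <- function(window, model) {
  W <- nchar(window); L <- nchar(model$consensus)
  cons <- strsplit(model$consensus, "")[[1]]
  wch <- strsplit(window, "")[[1]]
  best <- 0L
  found <- FALSE
  for (sp in model$spacer_min:model$spacer_max) {
    e <- W - sp
    if (e < 1L) next
    found <- TRUE
    score <- 0L
    for (k in seq_len(L)) {
      p <- e - L + k
      if (p >= 1L && wch[p] == cons[k]) score <- score + 1L
    }
    best <- max(best, score)
  }
  if (!found) 0L else best
}

# all fully-silent variants of an in-frame tail (character vector)
oracle_silent_variants <- function(tail, table) {
  cods <- substring(tail, seq(1, nchar(tail), 3), seq(3, nchar(tail), 3))
  fams <- lapply(cods, function(cd) {
    names(table$code)[table$code == table$code[[cd]]]
  })
  combos <- expand.grid(fams, stringsAsFactors = FALSE)
  apply(combos, 1L, paste, collapse = "")
}

# inverted repeats via complement-matrix anti-diagonal runs (a different
# formulation from the implementation's center-extension scan)
oracle_hairpins <- function(seq, min_stem, loop_min, loop_max) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- data.frame(stem_len = integer(0), pos5 = integer(0),
                    pos3 = integer(0), loop_len = integer(0))
  for (d in 3L:(2L * n)) {                # d = i + j of a complementary pair
    rows <- max(1L, d - n):min(n, d - 1L)
    rows <- rows[rows < d - rows]         # keep i < j half
    if (length(rows) == 0L) next
    ok <- vapply(rows, function(i) comp[[s[i]]] == s[d - i], TRUE)
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (q in which(r$values)) {
      run_rows <- rows[starts[q]:ends[q]]   # increasing i, shrinking loop
      i_out <- run_rows[1L]                 # outermost pair in this run
      i_in <- run_rows[length(run_rows)]    # innermost pair
      for (L in loop_min:loop_max) {
        if ((d - L - 1L) %% 2L != 0L) next
        r0 <- (d - L - 1L) %/% 2L           # innermost row for loop L
        if (!(r0 %in% run_rows)) next
        # inward-extendable (loop L-2 also pairs) => not maximal for L
        if (L - 2L >= loop_min && (r0 + 1L) %in% run_rows) next
        k <- r0 - i_out + 1L
        if (k >= min_stem) {
          out <- rbind(out, data.frame(stem_len = k, pos5 = r0 - k + 1L,
                                       pos3 = d - r0, loop_len = L))
        }
      }
    }
  }
  out <- out[order(out$pos5, out$pos3), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# eligibility by per-base outward scan (not rle): base i is eligible when
# some window of w consecutive identical bases contains it
oracle_p_desired <- function(mask, muts, w) {
  n <- length(mask)
  eligible <- logical(n)
  for (i in seq_len(n)) {
    if (!mask[i]) next
    left <- i
    while (left > 1L && mask[left - 1L]) left <- left - 1L
    right <- i
    while (right < n && mask[right + 1L]) right <- right + 1L
    eligible[i] <- (right - left + 1L) >= w
  }
  ne <- sum(eligible)
  if (ne == 0L) stop("no eligible base")
  sum(eligible & seq_len(n) > max(muts)) / ne
}

oracle_eligible_segments <- function(mask, w) {
  n <- length(mask)
  segs <- data.frame(start = integer(0), end = integer(0))
  i <- 1L
  while (i <= n) {
    if (mask[i]) {
      j <- i
      while (j < n && mask[j + 1L]) j <- j + 1L
      if (j - i + 1L >= w) segs <- rbind(segs, data.frame(start = i, end = j))
      i <- j + 1L
    } else i <- i + 1L
  }
  rownames(segs) <- NULL
  segs
}
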