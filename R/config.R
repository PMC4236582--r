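# Design configuration: one flat list of every tunable default, readable
# from / writable to a flat key=value file so that reports can embed an
# exact snapshot for provenance.

#' Design configuration
#'
#' Returns the default configuration, with any supplied overrides applied.
#' Fields (units in brackets):
#'
#' * `hr_len` [bp]: HR1/HR2 homology length, default 100 (50 is accepted
#'   with a validation warning).
#' * `hr3_len` [bp]: target HR3 length, default 40; bounds
#'   `hr3_min`/`hr3_max` = 30/50 are enforced.
#' * `frag_len` [bp]: approximate target-gene content of each mutation
#'   fragment, default 200.
#' * `n_terminators`: terminators ahead of the I-SceI site in the
#'   selection cassette (0, 1 or 2), default 2.
#' * `w_max` [bp]: maximum exact window a recoded fragment may share with
#'   the original, default 14.
#' * `w_integration` [bp]: minimal pairing window for the crossover-
#'   position model, default 20.
#' * `p_threshold`: minimum acceptable desired-integration probability,
#'   default 0.9.
#' * `rbs_consensus`, `rbs_spacer_min`, `rbs_spacer_max`: Shine-Dalgarno
#'   model (AGGAGG, spacer 4-13 nt).
#' * `hairpin_min_stem` [bp], `hairpin_loop_min`, `hairpin_loop_max`:
#'   inverted-repeat screen defaults (8, 3, 10).
#' * `overlap_len` [bp]: Gibson junction overlap, default 20.
#' * `tm_target` [degC], `tm_delta` [degC], `primer_min_len`,
#'   `primer_max_len`: amplification-primer defaults (60, 3, 18, 35).
#' * `tm_na_mM`, `tm_primer_nM`: nearest-neighbor Tm conditions (200 mM
#'   effective monovalent ionic strength, a PCR-buffer-equivalent
#'   default; 250 nM primer).
#' * `marker`: default selection marker part name (`cat`).
#' * `cat_orf_gap` [bp]: gap between marker stop codon and the restored
#'   ORF start in marker-promoter designs, default 0.
#'
#' @param ... name = value overrides.
#' @return a `design_config` list.
#' @export
design_config <- function(...) {
  cfg <- list(
    hr_len = 100L, hr3_len = 40L, hr3_min = 30L, hr3_max = 50L,
    frag_len = 200L, n_terminators = 2L,
    w_max = 14L, w_integration = 20L, p_threshold = 0.9,
    rbs_consensus = "AGGAGG", rbs_spacer_min = 4L, rbs_spacer_max = 13L,
    hairpin_min_stem = 8L, hairpin_loop_min = 3L, hairpin_loop_max = 10L,
    overlap_len = 20L, tm_target = 60, tm_delta = 3,
    primer_min_len = 18L, primer_max_len = 35L,
    tm_na_mM = 200, tm_primer_nM = 250,
    marker = "cat", cat_orf_gap = 0L
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over))) {
    over <- over[[1]]
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- modifyList(cfg, over)
  int_keys <- c("hr_len", "hr3_len", "hr3_min", "hr3_max", "frag_len",
                "n_terminators", "w_max", "w_integration", "rbs_spacer_min",
                "rbs_spacer_max", "hairpin_min_stem", "hairpin_loop_min",
                "hairpin_loop_max", "overlap_len", "primer_min_len",
                "primer_max_len", "cat_orf_gap")
  cfg[int_keys] <- lapply(cfg[int_keys], as.integer)
  stopifnot(cfg$hr3_min <= cfg$hr3_len, cfg$hr3_len <= cfg$hr3_max,
            cfg$n_terminators %in% 0:2, cfg$w_max >= 3L,
            cfg$w_integration >= 1L, cfg$p_threshold >= 0,
            cfg$p_threshold <= 1, cfg$rbs_spacer_min >= 1L,
            cfg$rbs_spacer_min <= cfg$rbs_spacer_max,
            nchar(cfg$rbs_consensus) >= 4L, cfg$hairpin_min_stem >= 3L)
  structure(cfg, class = "design_config")
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` comments and blank lines ignored.
#' Values are parsed as numbers where possible, otherwise kept as strings.
#'
#' @param path config file.
#' @return a [design_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 0L) < 2L
  if (any(bad)) {
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="), ""))
  parsed <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else gsub('^"|"$', "", v)
  })
  design_config(setNames(parsed, keys))
}

#' Write a configuration snapshot
#' @param config a [design_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "design_config"))
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    v <- if (is.character(v)) paste0('"', v, '"') else format(v, digits = 15)
    paste0(k, " = ", v)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

config_hash <- function(config) rlang::hash(unclass(config))
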