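#' Curation filter configuration
#'
#' Defaults mirror the standard animal-barcode curation settings: sequence
#' lengths between 100 bp (shortest useful mini-barcode) and 60 kbp
#' (about the longest known mitochondrial genome) inclusive; at most five
#' internal ambiguous `N` bases after terminal-N trimming; the stop-codon
#' check restricted to the profile-match envelope; the length window
#' applied to both sources; and the 80% CDS-overlap threshold for ENA
#' annotation consistency.
#'
#' @param min_len,max_len inclusive nucleotide length window.
#' @param max_internal_n maximum internal `N` count that still passes.
#' @param apply_length_to `"both"` or `"ENA_only"`.
#' @param stop_check_scope `"envelope"` or `"full_frame"`.
#' @param cds_overlap_min minimum shared fraction of CDS sites.
#' @param no_cds_policy ENA records with no CDS annotation:
#'   `"keep_on_hmm"` (default) or `"reject"`.
#' @param tc_override optional manual bit-score threshold replacing the
#'   profile's TC.
#' @return a `coi_filter_config` list.
#' @export
filter_config <- function(min_len = 100L, max_len = 60000L,
                          max_internal_n = 5L,
                          apply_length_to = c("both", "ENA_only"),
                          stop_check_scope = c("envelope", "full_frame"),
                          cds_overlap_min = 0.8,
                          no_cds_policy = c("keep_on_hmm", "reject"),
                          tc_override = NULL) {
  stopifnot(min_len > 0L, min_len <= max_len, max_internal_n >= 0L,
            cds_overlap_min >= 0, cds_overlap_min <= 1)
  structure(list(min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 max_internal_n = as.integer(max_internal_n),
                 apply_length_to = match.arg(apply_length_to),
                 stop_check_scope = match.arg(stop_check_scope),
                 cds_overlap_min = cds_overlap_min,
                 no_cds_policy = match.arg(no_cds_policy),
                 tc_override = tc_override),
            class = "coi_filter_config")
}

#' Length gate
#'
#' Pass iff `min_len <= length <= max_len` (both bounds inclusive). When
#' `cfg$apply_length_to == "ENA_only"`, BOLD records always pass.
#'
#' @param record a `coi_record`.
#' @param cfg a [filter_config()].
#' @return `TRUE`/`FALSE`.
#' @export
length_gate <- function(record, cfg = filter_config()) {
  if (cfg$apply_length_to == "ENA_only" && record$source != "ENA") return(TRUE)
  L <- nchar(record$sequence)
  L >= cfg$min_len && L <= cfg$max_len
}

#' Trim terminal runs of N
#'
#' Removes the maximal leading and trailing runs of `N` and returns the
#' counts. An all-N sequence trims to the empty string (by convention the
#' run counts as leading).
#'
#' @param sequence DNA string.
#' @return `list(sequence, n_leading, n_trailing)`.
#' @export
trim_terminal_n <- function(sequence) {
  lead <- attr(regexpr("^N*", sequence), "match.length")
  if (lead == nchar(sequence)) {
    return(list(sequence = "", n_leading = lead, n_trailing = 0L))
  }
  trail <- attr(regexpr("N*$", sequence), "match.length")
  list(sequence = substr(sequence, lead + 1L, nchar(sequence) - trail),
       n_leading = lead, n_trailing = trail)
}

#' Internal-N gate
#'
#' Pass iff the trimmed sequence contains at most `max_internal_n`
#' ambiguous `N` bases (strictly more than five fails under defaults).
#' Non-N IUPAC ambiguity codes are not counted.
#'
#' @param trimmed sequence after [trim_terminal_n()].
#' @param cfg a [filter_config()].
#' @return `TRUE`/`FALSE`.
#' @export
internal_n_gate <- function(trimmed, cfg = filter_config()) {
  n <- nchar(trimmed) - nchar(gsub("N", "", trimmed, fixed = TRUE))
  n <= cfg$max_internal_n
}

#' Stop-codon gate
#'
#' Fails when a stop (`*`) occurs inside the accepted profile-match
#' envelope of the winning frame peptide (`scope = "envelope"`), or
#' anywhere in that frame (`scope = "full_frame"`).
#'
#' @param hit a `coi_hit` carrying the winning frame peptide and envelope.
#' @param cfg a [filter_config()].
#' @return `TRUE`/`FALSE`.
#' @export
stop_codon_gate <- function(hit, cfg = filter_config()) {
  pep <- hit$peptide
  if (is.na(pep) || !nzchar(pep)) return(TRUE)
  region <- if (cfg$stop_check_scope == "envelope") {
    substr(pep, hit$aa_start + 1L, hit$aa_end)
  } else {
    pep
  }
  !grepl("*", region, fixed = TRUE)
}
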