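#' Merge curated ENA and BOLD record sets
#'
#' Dereplicates across sources by versionless accession: an ENA accession
#' matching a BOLD record's GenBank accession yields one merged record of
#' provenance `"BOTH"`, taking the ENA sequence and feature data (the
#' side whose annotation the pipeline validated) while BOLD fills missing
#' metadata. BOLD records without an accession are keyed by their process
#' ID (`"BOLD_unique"`); unmatched ENA records become `"ENA_unique"`.
#' Duplicate accessions within one source collapse to the first occurrence
#' with a warning; BOLD records with neither accession nor process ID are
#' dropped and counted.
#'
#' @param ena_kept,bold_kept curated record lists from [curate_records()].
#' @return `list(records, dropped)`: `records` is a list of merged records
#'   (`record_id`, `provenance`, `sequence`, `contributing_ids`, the
#'   source records as `$ena`/`$bold`), `dropped` the number of unusable
#'   BOLD records.
#' @export
merge_sources <- function(ena_kept, bold_kept) {
  dedup <- function(recs, what) {
    keys <- vapply(recs, function(r) r$record_id, character(1))
    dup <- duplicated(keys)
    if (any(dup)) {
      warning("collapsing ", sum(dup), " duplicate ", what,
              " record id(s): ", paste(unique(keys[dup]), collapse = ", "))
    }
    recs[!dup]
  }
  ena_kept <- dedup(ena_kept, "ENA")
  bold_kept <- dedup(bold_kept, "BOLD")

  dropped <- 0L
  out <- list()
  ena_by_acc <- setNames(seq_along(ena_kept),
                         vapply(ena_kept, function(r) r$accession,
                                character(1)))
  bold_used <- logical(length(bold_kept))
  bold_acc <- vapply(bold_kept, function(r) r$accession %||% NA_character_,
                     character(1))

  for (i in seq_along(ena_kept)) {
    e <- ena_kept[[i]]
    j <- which(!is.na(bold_acc) & bold_acc == e$accession)
    if (length(j)) {
      b <- bold_kept[[j[1]]]
      bold_used[j] <- TRUE
      out[[length(out) + 1L]] <- structure(list(
        record_id = e$accession, provenance = "BOTH",
        sequence = e$sequence, accession = e$accession,
        process_id = b$process_id,
        contributing_ids = c(e$record_id, b$process_id),
        ena = e, bold = b), class = "coi_merged")
    } else {
      out[[length(out) + 1L]] <- structure(list(
        record_id = e$accession, provenance = "ENA_unique",
        sequence = e$sequence, accession = e$accession,
        process_id = NA_character_, contributing_ids = e$record_id,
        ena = e, bold = NULL), class = "coi_merged")
    }
  }
  for (j in seq_along(bold_kept)) {
    if (bold_used[j]) next
    b <- bold_kept[[j]]
    id <- b$accession %||% b$process_id
    if (is.na(id %||% NA)) {
      dropped <- dropped + 1L
      next
    }
    out[[length(out) + 1L]] <- structure(list(
      record_id = id, provenance = "BOLD_unique", sequence = b$sequence,
      accession = b$accession, process_id = b$process_id,
      contributing_ids = b$record_id, ena = NULL, bold = b),
      class = "coi_merged")
  }
  list(records = out, dropped = dropped)
}
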