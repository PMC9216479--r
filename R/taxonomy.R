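lineage_na <- function() {
  list(name = setNames(rep("NA", 7L), COI_RANKS),
       taxid = setNames(rep("NA", 7L), COI_RANKS))
}

#' Seven-rank lineage of a taxid
#'
#' Walks parent links to the root, filling each canonical rank (kingdom,
#' phylum, class, order, family, genus, species) from nodes whose rank
#' label matches exactly; intermediate ranks such as "subfamily" never
#' fill canonical slots. Unmatched ranks are `"NA"`, as is everything for
#' a taxid absent from the store (with a warning).
#'
#' @param taxid integer taxid.
#' @param store a `coi_taxstore`.
#' @return lineage: `list(name, taxid)`, each a length-7 character vector
#'   named by rank (taxids as strings, `"NA"` when unresolved).
#' @export
lineage_from_taxid <- function(taxid, store) {
  lin <- lineage_na()
  t <- as.character(taxid)
  if (is.na(taxid) || !(t %in% names(store$parent))) {
    if (!is.na(taxid)) warning("taxid ", taxid, " absent from taxonomy store")
    return(lin)
  }
  while (t %in% names(store$parent)) {
    r <- store$rank[[t]]
    if (!is.null(r) && r %in% COI_RANKS && lin$name[[r]] == "NA") {
      lin$name[[r]] <- store$name[[t]] %||% "NA"
      lin$taxid[[r]] <- t
    }
    p <- as.character(store$parent[[t]])
    if (identical(p, t)) break
    t <- p
  }
  lin
}

# Homonym rule: among candidate taxids for one name, prefer the one whose
# ancestry (scientific names, case-insensitive) contains another raw rank
# name from the record (the queried name itself is excluded: every
# candidate trivially carries it); deterministic and order-free because
# every candidate is tested against the same raw names.
resolve_homonym <- function(candidates, ranks, store, query = NULL) {
  raw <- tolower(unlist(ranks, use.names = FALSE))
  raw <- raw[!is.na(raw)]
  if (!is.null(query)) raw <- setdiff(raw, tolower(query))
  ok <- vapply(candidates, function(tid) {
    anc <- ancestors_of(tid, store)
    any(tolower(store$name[as.character(anc)]) %in% raw, na.rm = TRUE)
  }, logical(1))
  if (sum(ok) == 1L) candidates[ok] else NA_integer_
}

#' Resolve a merged record's harmonized lineage
#'
#' Accessioned records resolve through the accession-to-taxid mapping
#' (falling back to the flat file's `taxon:` db_xref). BOLD-only records
#' resolve by the lowest-rank raw name (species first, then genus, ...)
#' present in the reference taxonomy; homonyms are disambiguated by
#' ancestry against the record's raw higher ranks, or left unresolved.
#' Raw names with no match anywhere are kept verbatim with taxid `"NA"`.
#' `changed` is `TRUE` iff any raw BOLD rank name differs from the
#' resolved NCBI name at that rank.
#'
#' @param record a `coi_merged` record.
#' @param store a `coi_taxstore` with `acc2taxid` populated.
#' @return `list(lineage, changed, taxid)`.
#' @export
resolve_record_lineage <- function(record, store) {
  raw_ranks <- if (!is.null(record$bold)) record$bold$taxon$ranks else NULL

  taxid <- NA_integer_
  if (!is.na(record$accession %||% NA) &&
      record$accession %in% names(store$acc2taxid)) {
    taxid <- store$acc2taxid[[record$accession]]
  } else if (!is.null(record$ena)) {
    hint <- record$ena$taxon$taxid_hint %||% NA_integer_
    if (!is.na(hint) && as.character(hint) %in% names(store$parent)) {
      taxid <- as.integer(hint)
    }
  } else if (!is.null(raw_ranks)) {
    for (r in rev(COI_RANKS)) {
      nm <- raw_ranks[[r]]
      if (is.na(nm %||% NA)) next
      cand <- store$name2tax[[tolower(nm)]]
      if (is.null(cand)) next
      if (length(cand) > 1L) {
        cand <- resolve_homonym(cand, raw_ranks, store, query = nm)
        if (is.na(cand)) {
          warning("unresolvable homonym '", nm, "' for record ",
                  record$record_id)
          next
        }
      }
      taxid <- cand
      break
    }
  }

  lin <- lineage_from_taxid(taxid, store)

  # ranks the backbone left open keep their raw BOLD names, taxid "NA"
  if (!is.null(raw_ranks)) {
    for (r in COI_RANKS) {
      if (lin$name[[r]] == "NA" && !is.na(raw_ranks[[r]] %||% NA)) {
        lin$name[[r]] <- raw_ranks[[r]]
      }
    }
  }

  changed <- FALSE
  if (!is.null(raw_ranks)) {
    for (r in COI_RANKS) {
      raw <- raw_ranks[[r]]
      if (!is.na(raw %||% NA) && lin$taxid[[r]] != "NA" &&
          lin$name[[r]] != raw) {
        changed <- TRUE
        break
      }
    }
  }
  list(lineage = lin, changed = changed, taxid = taxid)
}

#' Report BOLD taxonomy updates against the NCBI backbone
#'
#' One row per changed rank per record (`record_id`, `rank`, `old_name`,
#' `new_name`); the count of distinct changed records is attached as the
#' attribute `n_changed_records`.
#'
#' @param records list of `coi_merged` records.
#' @param resolutions list of [resolve_record_lineage()] results, parallel
#'   to `records`.
#' @return data.frame of changes.
#' @export
taxonomy_update_report <- function(records, resolutions) {
  rows <- list()
  for (i in seq_along(records)) {
    raw <- if (!is.null(records[[i]]$bold)) records[[i]]$bold$taxon$ranks
           else NULL
    if (is.null(raw)) next
    lin <- resolutions[[i]]$lineage
    for (r in COI_RANKS) {
      if (!is.na(raw[[r]] %||% NA) && lin$taxid[[r]] != "NA" &&
          lin$name[[r]] != raw[[r]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          record_id = records[[i]]$record_id, rank = r,
          old_name = raw[[r]], new_name = lin$name[[r]],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(record_id = character(), rank = character(),
               old_name = character(), new_name = character(),
               stringsAsFactors = FALSE)
  attr(out, "n_changed_records") <- length(unique(out$record_id))
  out
}
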