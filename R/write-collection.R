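#' Write the final collection as FASTA + TSV
#'
#' FASTA headers are bare record ids (written through Biostrings). The
#' TSV carries, per record: id, source (`BOLD`/`ENA`/`BOTH`), the seven
#' rank names and taxids (`"NA"` when unresolved), and the nine metadata
#' fields. Rows are sorted by record id for deterministic output. Records
#' lacking a lineage or metadata entry are emitted with `"NA"` fields and
#' a warning.
#'
#' @param records list of `coi_merged` records.
#' @param resolutions named list (by record id) of
#'   [resolve_record_lineage()] results; a parallel unnamed list is also
#'   accepted.
#' @param metadata named (or parallel) list of [build_metadata()] results.
#' @param out_fasta,out_tsv output paths.
#' @return invisibly, the TSV as a data.frame.
#' @export
write_collection <- function(records, resolutions, metadata, out_fasta,
                             out_tsv) {
  ids <- vapply(records, function(r) r$record_id, character(1))
  if (is.null(names(resolutions)) && length(resolutions)) {
    names(resolutions) <- ids
  }
  if (is.null(names(metadata)) && length(metadata)) names(metadata) <- ids

  ord <- order(ids)
  records <- records[ord]
  ids <- ids[ord]

  seqs <- vapply(records, function(r) r$sequence, character(1))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(seqs, ids)), out_fasta)

  md_fields <- c("seq_length", "mito_gencode", "country", "region", "host",
                 "collection_year", "collection_date", "lat_dd", "lon_dd",
                 "permalink")
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    src <- switch(r$provenance, BOLD_unique = "BOLD", ENA_unique = "ENA",
                  BOTH = "BOTH")
    res <- resolutions[[r$record_id]]
    if (is.null(res)) {
      warning("no lineage for record ", r$record_id, "; writing NA fields")
      lin <- lineage_na()
    } else {
      lin <- res$lineage
    }
    md <- metadata[[r$record_id]]
    if (is.null(md)) {
      warning("no metadata for record ", r$record_id, "; writing NA fields")
      md <- setNames(as.list(rep("NA", length(md_fields))), md_fields)
    }
    row <- c(list(record_id = r$record_id, source = src),
             as.list(setNames(lin$name, COI_RANKS)),
             as.list(setNames(lin$taxid, paste0(COI_RANKS, "_taxid"))),
             md[md_fields])
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    empty_collection_frame(md_fields)
  write.table(df, out_tsv, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(df)
}

empty_collection_frame <- function(md_fields) {
  cols <- c("record_id", "source", COI_RANKS, paste0(COI_RANKS, "_taxid"),
            md_fields)
  df <- as.data.frame(setNames(rep(list(character()), length(cols)), cols),
                      stringsAsFactors = FALSE)
  df
}
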