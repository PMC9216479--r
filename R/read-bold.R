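#' Default BOLD column mapping
#'
#' BOLD TSV exports have varied column names across vintages; the reader
#' therefore takes an explicit mapping from logical fields to column
#' names. These defaults follow the classic specimen+sequence combined
#' export. BOLD dumps carry no kingdom column (all records are animals),
#' so the `kingdom` entry may be `NA`.
#'
#' @return named list mapping logical field names to TSV column names.
#' @export
bold_column_map <- function() {
  list(process_id = "processid",
       accession = "genbank_accession",
       nucleotides = "nucleotides",
       marker = "markercode",
       kingdom = NA_character_,
       phylum = "phylum_name",
       class = "class_name",
       order = "order_name",
       family = "family_name",
       genus = "genus_name",
       species = "species_name",
       lat = "lat",
       lon = "lon",
       country = "country",
       region = "exactsite",
       collection_date = "collectiondate")
}

#' Read a BOLD-style TSV dump into sequence records
#'
#' One record per row whose marker code equals `marker` (default
#' `"COI-5P"`, the 5' barcode fragment of COI). Alignment gaps (`-`) and
#' whitespace are stripped from the nucleotide field on ingest; rank names
#' land in the record's raw taxonomy, geographic and date columns in its
#' raw metadata. Rows with an empty nucleotide field are skipped and
#' counted.
#'
#' @param path path to a tab-separated file with a header row.
#' @param column_map see [bold_column_map()].
#' @param marker marker code to retain.
#' @return `list(records, skipped_empty, skipped_marker)`.
#' @export
read_bold_tsv <- function(path, column_map = bold_column_map(),
                          marker = "COI-5P") {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   quote = "", na.strings = c("NA", ""),
                   colClasses = "character")
  mandatory <- c("process_id", "nucleotides", "marker")
  for (f in mandatory) {
    col <- column_map[[f]]
    if (is.null(col) || is.na(col) || !(col %in% names(df))) {
      stop("BOLD input lacks mandatory column for '", f, "' (",
           if (is.null(col) || is.na(col)) "unmapped" else col, ")")
    }
  }
  col <- function(f, i) {
    cn <- column_map[[f]]
    if (is.null(cn) || is.na(cn) || !(cn %in% names(df))) return(NA_character_)
    v <- df[[cn]][i]
    if (is.null(v) || is.na(v) || !nzchar(trimws(v))) NA_character_ else trimws(v)
  }

  records <- list()
  skipped_empty <- 0L
  skipped_marker <- 0L
  for (i in seq_len(nrow(df))) {
    mk <- col("marker", i)
    if (is.na(mk) || mk != marker) {
      skipped_marker <- skipped_marker + 1L
      next
    }
    nt <- col("nucleotides", i)
    nt <- if (is.na(nt)) "" else toupper(gsub("[-\\s]|[[:space:]]", "", nt))
    if (!nzchar(nt)) {
      skipped_empty <- skipped_empty + 1L
      next
    }
    pid <- col("process_id", i)
    acc <- col("accession", i)
    if (!is.na(acc)) acc <- strip_version(acc)
    rid <- if (!is.na(acc)) acc else pid
    if (is.na(rid)) {
      skipped_empty <- skipped_empty + 1L
      next
    }
    ranks <- setNames(vapply(COI_RANKS, function(r) col(r, i), character(1)),
                      COI_RANKS)
    meta <- list(lat = col("lat", i), lon = col("lon", i),
                 country = col("country", i), region = col("region", i),
                 collection_date = col("collection_date", i))
    records[[length(records) + 1L]] <- new_record(
      record_id = rid, source = "BOLD", accession = acc, process_id = pid,
      sequence = nt, features = list(),
      taxon = list(organism = ranks[["species"]], taxid_hint = NA_integer_,
                   ranks = ranks),
      metadata = meta)
  }
  list(records = records, skipped_empty = skipped_empty,
       skipped_marker = skipped_marker)
}
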