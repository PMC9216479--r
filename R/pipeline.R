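#' Pipeline configuration
#'
#' Collects input paths, filter settings and output location for
#' [run_pipeline()]. `ena` may list several flat files. `blast = NULL` (or
#' `skip_contamination = TRUE`) skips the contamination stage.
#'
#' @param ena character vector of EMBL flat-file paths (may be empty).
#' @param bold path to a BOLD-style TSV (or `NULL`).
#' @param hmm path to the HMMER3 ASCII profile.
#' @param taxdump directory with `nodes.dmp`/`names.dmp`/`gencode.dmp`.
#' @param acc2taxid path to the accession2taxid TSV.
#' @param blast optional BLAST tabular path.
#' @param out_dir output directory.
#' @param filters a [filter_config()].
#' @param skip_contamination ignore `blast` even when supplied.
#' @param marker BOLD marker code to retain.
#' @return a `coi_pipeline_config` list.
#' @export
pipeline_config <- function(ena = character(), bold = NULL, hmm, taxdump,
                            acc2taxid, blast = NULL, out_dir,
                            filters = filter_config(),
                            skip_contamination = FALSE,
                            marker = "COI-5P") {
  cfg <- list(ena = ena, bold = bold, hmm = hmm, taxdump = taxdump,
              acc2taxid = acc2taxid, blast = blast, out_dir = out_dir,
              filters = filters, skip_contamination = skip_contamination,
              marker = marker)
  for (f in c(cfg$ena, cfg$bold, cfg$hmm, cfg$acc2taxid, cfg$blast)) {
    if (!is.null(f) && !file.exists(f)) stop("missing input file: ", f)
  }
  if (!dir.exists(cfg$taxdump)) stop("missing taxdump directory: ",
                                     cfg$taxdump)
  structure(cfg, class = "coi_pipeline_config")
}

#' Run the curation pipeline end-to-end
#'
#' Reads all inputs, curates each source through the gate sequence,
#' merges and dereplicates, harmonizes taxonomy, assembles metadata and
#' writes the collection outputs into `out_dir`: `collection.fasta`,
#' `collection.tsv` (taxonomy + metadata), `synonyms.tsv`,
#' `taxonomy_updates.tsv`, `rejections.tsv`, `provenance.tsv`,
#' `composition.tsv` and `length_histogram.tsv`. Per-stage tallies are
#' reported through `message()`. An empty surviving set is a success with
#' empty outputs and a warning.
#'
#' @param config a [pipeline_config()] (or a named list/YAML path with the
#'   same fields).
#' @return invisibly, a list with the curation decisions, merged records,
#'   resolutions, summaries and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML config requires the yaml package")
    }
    y <- yaml::read_yaml(config)
    flt <- do.call(filter_config, y$filters %||% list())
    config <- do.call(pipeline_config,
                      c(y[setdiff(names(y), "filters")],
                        list(filters = flt)))
  }
  if (!inherits(config, "coi_pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  store <- read_taxdump(config$taxdump)
  store$acc2taxid <- read_acc2taxid(config$acc2taxid)
  profile <- read_hmm_profile(config$hmm)

  ena_records <- list()
  parse_errors <- list()
  for (f in config$ena) {
    r <- read_embl_flatfile(f)
    ena_records <- c(ena_records, r$records)
    parse_errors[[length(parse_errors) + 1L]] <- r$errors
  }
  bold_records <- if (!is.null(config$bold)) {
    read_bold_tsv(config$bold, marker = config$marker)$records
  } else {
    list()
  }
  message(sprintf("ingested %d ENA and %d BOLD records",
                  length(ena_records), length(bold_records)))

  blast_hits <- if (!is.null(config$blast) && !config$skip_contamination) {
    read_blast_tab(config$blast)
  } else {
    NULL
  }

  cur_ena <- curate_records(ena_records, profile, store, config$filters,
                            blast_hits)
  cur_bold <- curate_records(bold_records, profile, store, config$filters,
                             blast_hits)
  decisions <- rbind(cur_ena$decisions, cur_bold$decisions)
  if (!is.null(decisions)) {
    tal <- table(ifelse(decisions$kept, "kept", decisions$stage))
    message("curation: ", paste(names(tal), tal, sep = "=", collapse = ", "))
  }

  merged <- merge_sources(cur_ena$records, cur_bold$records)
  if (!length(merged$records)) {
    warning("no records survived curation; writing empty outputs")
  }

  resolutions <- lapply(merged$records, resolve_record_lineage, store = store)
  names(resolutions) <- vapply(merged$records, function(r) r$record_id,
                               character(1))
  metadata <- lapply(seq_along(merged$records), function(i) {
    build_metadata(merged$records[[i]], resolutions[[i]], store)
  })
  names(metadata) <- names(resolutions)

  out <- function(f) file.path(config$out_dir, f)
  collection <- write_collection(merged$records, resolutions, metadata,
                                 out("collection.fasta"),
                                 out("collection.tsv"))

  synonyms <- harvest_synonyms(cur_ena$synonym_overlaps)
  writeLines(c("synonym", synonyms), out("synonyms.tsv"))

  updates <- taxonomy_update_report(merged$records, resolutions)
  write.table(updates, out("taxonomy_updates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  rejections <- decisions[!is.na(decisions$stage) & !decisions$kept,
                          c("record_id", "stage", "reason")]
  write.table(rejections, out("rejections.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  prov <- provenance_summary(merged$records)
  write.table(prov, out("provenance.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  comp <- composition_by_rank(lapply(resolutions, `[[`, "lineage"))
  write.table(comp, out("composition.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  lh <- length_histogram(merged$records)
  write.table(lh$histogram, out("length_histogram.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  invisible(list(decisions = decisions, trail = rbind(cur_ena$trail,
                                                      cur_bold$trail),
                 merged = merged$records, resolutions = resolutions,
                 metadata = metadata, collection = collection,
                 synonyms = synonyms, updates = updates,
                 provenance = prov, composition = comp,
                 length_histogram = lh,
                 parse_errors = do.call(rbind, parse_errors),
                 out_dir = config$out_dir))
}
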