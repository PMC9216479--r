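#' Parse BLAST tabular output, keeping the best hit per query
#'
#' Reads an outfmt-6-like tab-separated file. Best = maximal bitscore,
#' ties resolved by first occurrence. With `has_taxid_col = TRUE` the
#' subject taxid is taken from the column after the standard twelve
#' (`-outfmt "6 std staxids"`). Malformed rows are skipped with a warning.
#'
#' @param path path to the tabular file.
#' @param has_taxid_col whether a subject-taxid column follows the
#'   standard twelve fields.
#' @return named list keyed by query id:
#'   `list(subject_id, subject_taxid, bitscore, pident, evalue)`.
#' @export
read_blast_tab <- function(path, has_taxid_col = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  hits <- list()
  for (l in lines) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 12) {
      warning("malformed BLAST row skipped: ", substr(l, 1, 60))
      next
    }
    bits <- suppressWarnings(as.numeric(f[12]))
    if (is.na(bits)) {
      warning("malformed BLAST row skipped (bitscore): ", substr(l, 1, 60))
      next
    }
    taxid <- if (has_taxid_col && length(f) >= 13) {
      suppressWarnings(as.integer(strsplit(f[13], ";")[[1]][1]))
    } else {
      NA_integer_
    }
    q <- f[1]
    if (is.null(hits[[q]]) || bits > hits[[q]]$bitscore) {
      hits[[q]] <- list(subject_id = f[2], subject_taxid = taxid,
                        bitscore = bits,
                        pident = suppressWarnings(as.numeric(f[3])),
                        evalue = suppressWarnings(as.numeric(f[11])))
    }
  }
  hits
}

#' Default contamination reject clades
#'
#' Root taxids of Bacteria, Archaea and Viridiplantae in the supplied
#' taxonomy store, looked up by scientific name so the defaults adapt to
#' whatever taxdump is in use.
#'
#' @param store a `coi_taxstore`.
#' @return integer vector of taxids (possibly shorter than three when a
#'   clade is absent from the store).
#' @export
default_reject_clades <- function(store) {
  unlist(lapply(c("bacteria", "archaea", "viridiplantae"),
                function(n) store$name2tax[[n]]), use.names = FALSE)
}

#' Contamination gate
#'
#' Fails a record iff its best nucleotide-similarity hit has an
#' ancestor-or-self among the reject clades (bacterial, archaeal or plant
#' by default). Queries with no hit pass; hits whose taxid is absent from
#' the store pass with a warning (they cannot be classified).
#'
#' @param record_id query id.
#' @param hits parsed hits from [read_blast_tab()].
#' @param store a `coi_taxstore`.
#' @param reject_clades integer taxids; see [default_reject_clades()].
#' @return `TRUE` (pass) / `FALSE` (contaminated).
#' @export
contamination_gate <- function(record_id, hits, store,
                               reject_clades = default_reject_clades(store)) {
  h <- hits[[record_id]]
  if (is.null(h)) return(TRUE)
  taxid <- h$subject_taxid
  if (is.na(taxid)) return(TRUE)
  if (!(as.character(taxid) %in% names(store$parent))) {
    warning("subject taxid ", taxid, " absent from taxonomy; record ",
            record_id, " passes contamination screen unclassified")
    return(TRUE)
  }
  !any(ancestors_of(taxid, store) %in% reject_clades)
}

# ancestor-or-self taxids up to the root
ancestors_of <- function(taxid, store) {
  out <- integer()
  t <- as.character(taxid)
  while (t %in% names(store$parent)) {
    out <- c(out, as.integer(t))
    p <- as.character(store$parent[[t]])
    if (identical(p, t)) break
    t <- p
  }
  out
}
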