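#' Read an EMBL flat file into sequence records
#'
#' Parses the standard-release EMBL flat-file dialect (`ID`/`AC`/`OS`/`FT`/
#' `SQ` lines, entries terminated by `//`). For each entry the ID line
#' supplies the accession (stored versionless) and declared length; `CDS`
#' and `gene` features are collected with their `/gene`, `/product` and
#' `/pseudo`//`/pseudogene` qualifiers; the source feature contributes the
#' organism, `taxon:` db_xref and the country, lat_lon, host and
#' collection_date qualifiers. Locations `a..b`, `complement(a..b)` and
#' `join(...)` are supported; a `join` becomes multiple spans of one
#' feature, and partial-location markers (`<`, `>`) are stripped.
#' Coordinates convert from 1-based inclusive to 0-based half-open.
#'
#' Malformed entries (no ID line, declared length disagreeing with the
#' sequence block, truncated final entry) are skipped and reported, never
#' raised.
#'
#' @param path path to an EMBL flat file (plain text or gzip).
#' @return `list(records, errors)`: `records` is a list of sequence-record
#'   objects (class `coi_record`), `errors` a data.frame with columns
#'   `entry` and `reason`.
#' @export
read_embl_flatfile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^//\\s*$", lines)
  records <- list()
  errors <- data.frame(entry = character(), reason = character(),
                       stringsAsFactors = FALSE)
  note_error <- function(entry, reason) {
    errors[nrow(errors) + 1L, ] <<- list(entry, reason)
  }

  start <- 1L
  blocks <- lapply(ends, function(e) {
    b <- lines[start:(e - 1L)]
    start <<- e + 1L
    b
  })
  if (start <= length(lines) &&
      any(nzchar(trimws(lines[start:length(lines)])))) {
    note_error("<trailing>", "truncated final entry (no // terminator)")
  }

  for (block in blocks) {
    rec <- tryCatch(parse_embl_entry(block),
                    coi_parse_error = function(e) e)
    if (inherits(rec, "coi_parse_error")) {
      note_error(rec$entry %||% "<unknown>", conditionMessage(rec))
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  ids <- vapply(records, function(r) r$record_id, character(1))
  if (anyDuplicated(ids)) {
    warning("duplicate record ids within one flat file: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  list(records = records, errors = errors)
}

parse_error <- function(msg, entry = NULL) {
  stop(structure(class = c("coi_parse_error", "condition"),
                 list(message = msg, call = NULL, entry = entry)))
}

parse_embl_entry <- function(block) {
  idl <- grep("^ID   ", block, value = TRUE)
  if (length(idl) == 0L) parse_error("no ID line")
  parts <- strsplit(sub("^ID   ", "", idl[1]), ";")[[1]]
  accession <- strip_version(trimws(parts[1]))
  if (!nzchar(accession)) parse_error("empty accession on ID line")
  declared <- suppressWarnings(
    as.integer(sub(".*?(\\d+)\\s*BP\\.?\\s*$", "\\1", idl[1])))

  # sequence block
  sq <- grep("^SQ   ", block)
  sequence <- ""
  if (length(sq)) {
    seq_lines <- block[seq(sq[1] + 1L, length(block))]
    seq_lines <- seq_lines[grepl("^\\s", seq_lines)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  }
  if (!is.na(declared) && nchar(sequence) != declared) {
    parse_error(sprintf("sequence length %d != declared %d",
                        nchar(sequence), declared), entry = accession)
  }

  ft <- parse_embl_features(block[grepl("^FT   ", block)], accession)

  organism <- grep("^OS   ", block, value = TRUE)
  organism <- if (length(organism)) trimws(sub("^OS   ", "", organism[1])) else NA_character_

  new_record(record_id = accession, source = "ENA", accession = accession,
             process_id = NA_character_, sequence = sequence,
             features = ft$features,
             taxon = list(organism = ft$organism %||% organism,
                          taxid_hint = ft$taxid_hint, ranks = NULL),
             metadata = ft$metadata)
}

parse_embl_features <- function(ft_lines, accession) {
  features <- list()
  metadata <- list()
  organism <- NULL
  taxid_hint <- NA_integer_

  cur_key <- NULL
  cur_loc <- ""
  cur_quals <- list()
  open_qual <- NULL
  in_loc <- FALSE

  flush_feature <- function() {
    if (is.null(cur_key)) return()
    quals <- cur_quals
    if (cur_key %in% c("CDS", "gene")) {
      loc <- parse_embl_location(cur_loc, accession)
      features[[length(features) + 1L]] <<- new_cds(
        key = cur_key, spans = loc$spans, strand = loc$strand,
        gene = qual1(quals, "gene"), product = qual1(quals, "product"),
        pseudo = any(c("pseudo", "pseudogene") %in% names(quals)))
    } else if (cur_key == "source") {
      organism <<- qual1(quals, "organism")
      for (f in c("country", "lat_lon", "host", "collection_date")) {
        v <- qual1(quals, f)
        if (!is.na(v)) metadata[[f]] <<- v
      }
      xr <- gsub('^"|"$', "",
                 unlist(quals[names(quals) == "db_xref"], use.names = FALSE))
      tx <- grep("^taxon:", xr, value = TRUE)
      if (length(tx)) taxid_hint <<- as.integer(sub("^taxon:", "", tx[1]))
    }
  }

  for (line in ft_lines) {
    key <- trimws(substr(line, 6L, 20L))
    rest <- trimws(substr(line, 22L, nchar(line)))
    if (nzchar(key)) {
      flush_feature()
      cur_key <- key
      cur_loc <- rest
      cur_quals <- list()
      open_qual <- NULL
      in_loc <- TRUE
    } else if (startsWith(rest, "/")) {
      in_loc <- FALSE
      m <- regmatches(rest, regexec("^/([A-Za-z_0-9]+)(=(.*))?$", rest))[[1]]
      qname <- m[2]
      qval <- if (nchar(m[3])) m[4] else ""
      cur_quals[[length(cur_quals) + 1L]] <- qval
      names(cur_quals)[length(cur_quals)] <- qname
      open_qual <- length(cur_quals)
    } else if (in_loc) {
      cur_loc <- paste0(cur_loc, rest)
    } else if (!is.null(open_qual)) {
      cur_quals[[open_qual]] <- paste(cur_quals[[open_qual]], rest)
    }
  }
  flush_feature()

  list(features = features, metadata = metadata,
       organism = organism, taxid_hint = taxid_hint)
}

qual1 <- function(quals, name) {
  v <- unlist(quals[names(quals) == name], use.names = FALSE)
  if (!length(v)) return(NA_character_)
  trimws(gsub('^"|"$', "", v[1]))
}

# "a..b", "complement(a..b)", "join(a..b,c..d)", single-base "a";
# partial markers (< >) stripped. Returns 0-based half-open spans.
parse_embl_location <- function(loc, accession = NULL) {
  loc <- gsub("[<>\\s]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",")[[1]]
  spans <- matrix(NA_integer_, nrow = length(parts), ncol = 2L)
  for (i in seq_along(parts)) {
    p <- parts[i]
    if (grepl("^\\d+\\.\\.\\d+$", p)) {
      ab <- as.integer(strsplit(p, "\\.\\.")[[1]])
    } else if (grepl("^\\d+$", p)) {
      ab <- c(as.integer(p), as.integer(p))
    } else {
      parse_error(paste("unsupported location:", p), entry = accession)
    }
    if (ab[1] > ab[2]) parse_error(paste("inverted location:", p),
                                   entry = accession)
    spans[i, ] <- c(ab[1] - 1L, ab[2])  # 1-based inclusive -> 0-based half-open
  }
  list(spans = spans, strand = strand)
}

strip_version <- function(acc) sub("\\.\\d+$", "", acc)

new_record <- function(record_id, source, accession, process_id, sequence,
                       features = list(), taxon = list(), metadata = list()) {
  structure(list(record_id = record_id, source = source,
                 accession = accession, process_id = process_id,
                 sequence = sequence, features = features,
                 taxon = taxon, metadata = metadata),
            class = "coi_record")
}

new_cds <- function(key, spans, strand, gene = NA_character_,
                    product = NA_character_, pseudo = FALSE) {
  structure(list(key = key, spans = spans, strand = strand,
                 gene = gene, product = product, pseudo = pseudo),
            class = "coi_cds")
}

#' @export
print.coi_record <- function(x, ...) {
  cat(sprintf("<coi_record %s [%s] %d nt, %d feature(s)>\n",
              x$record_id, x$source, nchar(x$sequence), length(x$features)))
  invisible(x)
}
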