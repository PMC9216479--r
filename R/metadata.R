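#' Parse geographic coordinates to signed decimal degrees
#'
#' Accepts the EMBL `lat_lon` qualifier dialect (`"45.5 N 9.2 E"`), a DMS
#' string (`"45 30 0 S 9 15 0 W"`, converted as deg + min/60 + sec/3600)
#' or a numeric lat/lon pair. South and west hemispheres are negative.
#' Out-of-range or unparseable input yields `NULL`, never an error.
#'
#' @param raw character string, or numeric vector of length 2 (lat, lon).
#' @return `c(lat_dd, lon_dd)` or `NULL`.
#' @export
parse_coordinates <- function(raw) {
  if (is.numeric(raw) && length(raw) == 2L) {
    return(check_dd(raw[1], raw[2]))
  }
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) return(NULL)
  s <- trimws(raw)
  num <- "[0-9]+(?:\\.[0-9]+)?"

  m <- regmatches(s, regexec(
    sprintf("^(%s)\\s*([NS])[ ,]+(%s)\\s*([EW])$", num, num), s))[[1]]
  if (length(m)) {
    lat <- as.numeric(m[2]) * ifelse(m[3] == "S", -1, 1)
    lon <- as.numeric(m[4]) * ifelse(m[5] == "W", -1, 1)
    return(check_dd(lat, lon))
  }

  m <- regmatches(s, regexec(
    sprintf("^(%s)\\s+(%s)\\s+(%s)\\s*([NS])[ ,]+(%s)\\s+(%s)\\s+(%s)\\s*([EW])$",
            num, num, num, num, num, num), s))[[1]]
  if (length(m)) {
    lat <- (as.numeric(m[2]) + as.numeric(m[3]) / 60 + as.numeric(m[4]) / 3600) *
      ifelse(m[5] == "S", -1, 1)
    lon <- (as.numeric(m[6]) + as.numeric(m[7]) / 60 + as.numeric(m[8]) / 3600) *
      ifelse(m[9] == "W", -1, 1)
    return(check_dd(lat, lon))
  }

  m <- regmatches(s, regexec(
    sprintf("^(-?%s)[ ,\t]+(-?%s)$", num, num), s))[[1]]
  if (length(m)) return(check_dd(as.numeric(m[2]), as.numeric(m[3])))
  NULL
}

check_dd <- function(lat, lon) {
  if (any(is.na(c(lat, lon)))) return(NULL)
  if (lat < -90 || lat > 90 || lon < -180 || lon > 180) {
    warning(sprintf("coordinates out of range: %s %s", lat, lon))
    return(NULL)
  }
  c(lat = lat, lon = lon)
}

COI_MONTHS <- setNames(1:12, c("JAN", "FEB", "MAR", "APR", "MAY", "JUN",
                               "JUL", "AUG", "SEP", "OCT", "NOV", "DEC"))

#' Parse a collection date
#'
#' Recognized dialects: `"DD-MMM-YYYY"` (EMBL), `"YYYY-MM-DD"` (ISO) and
#' bare `"YYYY"`. Two-digit years (`"DD-MMM-YY"`) are rejected as
#' ambiguous. The year is extracted whenever any dialect matches; a full
#' ISO date only for complete dates.
#'
#' @param raw character string.
#' @return `list(year, iso_date)`; `"NA"` strings when unparseable.
#' @export
parse_collection_date <- function(raw) {
  na <- list(year = "NA", iso_date = "NA")
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) return(na)
  s <- trimws(raw)

  m <- regmatches(s, regexec("^([0-9]{1,2})-([A-Za-z]{3})-([0-9]{4})$", s))[[1]]
  if (length(m)) {
    mon <- COI_MONTHS[toupper(m[3])]
    if (!is.na(mon)) {
      return(list(year = as.integer(m[4]),
                  iso_date = sprintf("%s-%02d-%02d", m[4], mon,
                                     as.integer(m[2]))))
    }
  }
  m <- regmatches(s, regexec("^([0-9]{4})-([0-9]{2})-([0-9]{2})$", s))[[1]]
  if (length(m)) {
    return(list(year = as.integer(m[2]), iso_date = s))
  }
  if (grepl("^[0-9]{4}$", s)) return(list(year = as.integer(s),
                                          iso_date = "NA"))
  na
}

#' Permalink URL templates
#'
#' `{accession}` / `{process_id}` placeholders are substituted per record.
#' Defaults follow the ENA browser and BOLD portal URL shapes.
#'
#' @param ena,bold template strings.
#' @return named list of templates.
#' @export
permalink_templates <- function(
    ena = "https://www.ebi.ac.uk/ena/browser/view/{accession}",
    bold = "http://www.boldsystems.org/index.php/Public_RecordView?processid={process_id}") {
  list(ena = ena, bold = bold)
}

#' Assemble the nine normalized metadata fields for a record
#'
#' Produces sequence length (of the final, trimmed sequence),
#' mitochondrial genetic-code id, country, sub-country region, host
#' species, collection year, complete collection date (ISO-8601),
#' decimal-degree coordinates (4 dp) and the source-database permalink.
#' The EMBL `country` qualifier splits at the first colon into
#' country/region; for records present in both sources ENA values take
#' precedence and BOLD fills the gaps. Missing fields are `"NA"`.
#'
#' @param record a `coi_merged` record.
#' @param resolution result of [resolve_record_lineage()] for the record.
#' @param store a `coi_taxstore`.
#' @param templates see [permalink_templates()].
#' @return named list of the nine fields (all character).
#' @export
build_metadata <- function(record, resolution, store,
                           templates = permalink_templates()) {
  ena_md <- if (!is.null(record$ena)) record$ena$metadata else list()
  bold_md <- if (!is.null(record$bold)) record$bold$metadata else list()

  country <- "NA"; region <- "NA"
  if (!is.na(ena_md$country %||% NA)) {
    parts <- strsplit(ena_md$country, ":", fixed = TRUE)[[1]]
    country <- trimws(parts[1])
    if (length(parts) > 1L) {
      region <- trimws(paste(parts[-1], collapse = ":"))
    }
  } else {
    country <- bold_md$country %||% "NA"
    region <- bold_md$region %||% "NA"
  }

  host <- ena_md$host %||% "NA"

  date_raw <- ena_md$collection_date %||% bold_md$collection_date %||% NA
  d <- parse_collection_date(if (is.na(date_raw)) NA_character_ else date_raw)

  dd <- NULL
  if (!is.na(ena_md$lat_lon %||% NA)) {
    dd <- parse_coordinates(ena_md$lat_lon)
  }
  if (is.null(dd) && !is.na(bold_md$lat %||% NA) &&
      !is.na(bold_md$lon %||% NA)) {
    dd <- parse_coordinates(c(as.numeric(bold_md$lat),
                              as.numeric(bold_md$lon)))
  }

  fill <- function(tmpl) {
    t <- gsub("{accession}", record$accession %||% "", tmpl, fixed = TRUE)
    gsub("{process_id}", record$process_id %||% "", t, fixed = TRUE)
  }
  permalink <- if (!is.null(record$ena)) fill(templates$ena) else
    fill(templates$bold)

  mito <- record$ena$mito_code %||% record$bold$mito_code %||% NA_integer_
  if (is.na(mito)) {
    mito <- attr(mito_code_for(resolution$taxid, store), "code_id")
  }

  list(seq_length = as.character(nchar(record$sequence)),
       mito_gencode = as.character(mito),
       country = country, region = region, host = host,
       collection_year = as.character(d$year),
       collection_date = d$iso_date,
       lat_dd = if (is.null(dd)) "NA" else sprintf("%.4f", dd[["lat"]]),
       lon_dd = if (is.null(dd)) "NA" else sprintf("%.4f", dd[["lon"]]),
       permalink = permalink)
}
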