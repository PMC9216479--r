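#' Percentage with an explicit rounding mode
#'
#' Published tables mix conventions (some truncate, some round half-up),
#' so reports pin the mode explicitly. `"half_up"` rounds 0.5 away from
#' zero (unlike base [round()]'s banker's rounding); `"truncate"` drops
#' digits beyond `digits`.
#'
#' @param count,total numerator and denominator.
#' @param digits decimal places.
#' @param mode `"half_up"` or `"truncate"`.
#' @return numeric percentage; `NA` when `total` is 0.
#' @export
pct_of <- function(count, total, digits = 2L,
                   mode = c("half_up", "truncate")) {
  mode <- match.arg(mode)
  if (length(total) == 1L && total == 0) return(rep(NA_real_, length(count)))
  x <- 100 * count / total
  f <- 10^digits
  switch(mode,
         half_up = sign(x) * floor(abs(x) * f + 0.5) / f,
         truncate = trunc(x * f) / f)
}

#' Provenance summary of a merged collection
#'
#' Counts and percentages of records unique to BOLD, unique to ENA, and
#' shared by both, in the style of a source-database provenance table.
#'
#' @param merged merged records from [merge_sources()].
#' @param digits,mode passed to [pct_of()].
#' @return data.frame with rows `BOLD_unique`, `ENA_unique`, `BOTH`,
#'   `total` and columns `count`, `pct`.
#' @export
provenance_summary <- function(merged, digits = 2L, mode = "half_up") {
  prov <- vapply(merged, function(r) r$provenance, character(1))
  counts <- c(BOLD_unique = sum(prov == "BOLD_unique"),
              ENA_unique = sum(prov == "ENA_unique"),
              BOTH = sum(prov == "BOTH"))
  total <- sum(counts)
  data.frame(category = c(names(counts), "total"),
             count = c(counts, total),
             pct = c(pct_of(counts, total, digits, mode),
                     if (total > 0) 100 else NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Taxonomic composition by phylum
#'
#' For each phylum (records with unresolved phylum group under `"NA"`):
#' the sequence count and the number of distinct class, order, family,
#' genus and species names, with percentages relative to the
#' collection-wide distinct totals at each rank. `"NA"` names are
#' excluded from distinct counts.
#'
#' @param lineages list of lineage objects (see [lineage_from_taxid()]).
#' @param digits,mode passed to [pct_of()].
#' @return data.frame, one row per phylum plus attribute `totals` (named
#'   vector of collection-wide distinct counts per rank).
#' @export
composition_by_rank <- function(lineages, digits = 3L, mode = "half_up") {
  sub_ranks <- c("class", "order", "family", "genus", "species")
  phyla <- vapply(lineages, function(l) l$name[["phylum"]], character(1))
  names_at <- function(lins, r) {
    v <- vapply(lins, function(l) l$name[[r]], character(1))
    unique(v[v != "NA"])
  }
  totals <- setNames(vapply(sub_ranks,
                            function(r) length(names_at(lineages, r)), 1L),
                     sub_ranks)
  rows <- lapply(sort(unique(phyla)), function(ph) {
    sub <- lineages[phyla == ph]
    row <- data.frame(phylum = ph, seq_count = length(sub),
                      stringsAsFactors = FALSE)
    for (r in sub_ranks) {
      n <- length(names_at(sub, r))
      row[[paste0(r, "_n")]] <- n
      row[[paste0(r, "_pct")]] <- if (totals[[r]] > 0) {
        pct_of(n, totals[[r]], digits, mode)
      } else 0
    }
    row
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(phylum = character(), seq_count = integer())
  }
  attr(out, "totals") <- totals
  out
}

#' Sequence-length histogram
#'
#' Exact integer histogram of final sequence lengths, with min, max and
#' mode (ties broken toward the smaller length).
#'
#' @param lengths integer vector of sequence lengths (or a list of merged
#'   records, whose sequences are measured).
#' @return `list(histogram, min, max, mode)`; `histogram` is a data.frame
#'   (`length`, `count`).
#' @export
length_histogram <- function(lengths) {
  if (is.list(lengths)) {
    lengths <- vapply(lengths, function(r) nchar(r$sequence), integer(1))
  }
  if (!length(lengths)) {
    return(list(histogram = data.frame(length = integer(), count = integer()),
                min = NA_integer_, max = NA_integer_, mode = NA_integer_))
  }
  tab <- table(lengths)
  hist <- data.frame(length = as.integer(names(tab)),
                     count = as.integer(tab))
  hist <- hist[order(hist$length), ]
  mode <- hist$length[which.max(hist$count)]  # first max = smallest length
  list(histogram = hist, min = min(lengths), max = max(lengths),
       mode = mode)
}
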