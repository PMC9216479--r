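#' Overlap between an annotated CDS and the profile footprint
#'
#' Computes the number of CDS nucleotide sites shared with the profile
#' HMM's nucleotide envelope. Multi-span (`join`) CDS locations contribute
#' the union of their spans; the denominator is the total number of CDS
#' sites, so the fraction answers "what share of the annotated coding
#' region does the profile match cover?". Strand is ignored (positional
#' comparison only). A zero-length CDS yields fraction 0 with a warning.
#'
#' @param cds a `coi_cds` feature (0-based half-open spans).
#' @param hit a `coi_hit` with nucleotide envelope `nt_start`/`nt_end`.
#' @return `list(cds_sites, shared_sites, fraction, gene, product)`.
#' @export
cds_profile_overlap <- function(cds, hit) {
  spans <- merge_spans(cds$spans)
  cds_sites <- sum(spans[, 2] - spans[, 1])
  shared <- sum(pmax(0L, pmin(spans[, 2], hit$nt_end) -
                       pmax(spans[, 1], hit$nt_start)))
  if (cds_sites == 0L) {
    warning("zero-length CDS; overlap fraction treated as 0")
    frac <- 0
  } else {
    frac <- shared / cds_sites
  }
  list(cds_sites = cds_sites, shared_sites = shared, fraction = frac,
       gene = cds$gene, product = cds$product)
}

# union of possibly-overlapping spans (matrix n x 2, half-open)
merge_spans <- function(spans) {
  if (nrow(spans) <= 1L) return(spans)
  spans <- spans[order(spans[, 1]), , drop = FALSE]
  out <- spans[1, , drop = FALSE]
  for (i in 2:nrow(spans)) {
    if (spans[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], spans[i, 2])
    } else {
      out <- rbind(out, spans[i, ])
    }
  }
  out
}

#' Validate an ENA record's CDS annotation against the profile match
#'
#' Among the record's CDS features, the one with maximal overlap fraction
#' decides the verdict: keep iff that fraction reaches the configured
#' threshold (at least 80% of CDS sites by default, inclusive). A decisive
#' CDS carrying a pseudogene tag rejects the record regardless of overlap.
#' Records with no CDS feature follow `cfg$no_cds_policy` (default: keep
#' on the profile-HMM evidence alone). All CDS features at or above the
#' threshold contribute their gene/product labels as synonym candidates.
#'
#' @param record an ENA `coi_record` whose hit passed the trusted cutoff.
#' @param hit the record's `coi_hit`.
#' @param cfg a [filter_config()].
#' @return `list(verdict, reason, best, qualifying)`: `verdict` one of
#'   `"keep"`/`"reject"`, `best` the decisive overlap result (or `NULL`),
#'   `qualifying` the overlap results of all threshold-passing CDS.
#' @export
validate_ena_record <- function(record, hit, cfg = filter_config()) {
  cds <- Filter(function(f) f$key == "CDS", record$features)
  if (!length(cds)) {
    v <- if (cfg$no_cds_policy == "keep_on_hmm") "keep" else "reject"
    return(list(verdict = v, reason = "no CDS annotation", best = NULL,
                qualifying = list()))
  }
  overlaps <- lapply(cds, cds_profile_overlap, hit = hit)
  fr <- vapply(overlaps, function(o) o$fraction, numeric(1))
  best_i <- which.max(fr)
  qualifying <- overlaps[fr >= cfg$cds_overlap_min &
                           !vapply(cds, function(f) f$pseudo, logical(1))]
  if (cds[[best_i]]$pseudo) {
    return(list(verdict = "reject", reason = "pseudogene tag on decisive CDS",
                best = overlaps[[best_i]], qualifying = qualifying))
  }
  if (fr[best_i] >= cfg$cds_overlap_min) {
    list(verdict = "keep",
         reason = sprintf("CDS overlap %.4f", fr[best_i]),
         best = overlaps[[best_i]], qualifying = qualifying)
  } else {
    list(verdict = "reject",
         reason = sprintf("CDS overlap %.4f < %.2f", fr[best_i],
                          cfg$cds_overlap_min),
         best = overlaps[[best_i]], qualifying = qualifying)
  }
}

#' Harvest COI gene-name synonyms
#'
#' Collects the `gene` and `product` labels of profile-consistent CDS
#' features from kept records into a case-preserving, whitespace-trimmed,
#' sorted unique list of potential COI gene-name synonyms.
#'
#' @param kept_overlaps list of overlap results (from the `qualifying`
#'   component of [validate_ena_record()]) across all kept ENA records.
#' @return sorted character vector.
#' @export
harvest_synonyms <- function(kept_overlaps) {
  labels <- unlist(lapply(kept_overlaps, function(o) c(o$gene, o$product)))
  labels <- trimws(labels[!is.na(labels)])
  sort(unique(labels[nzchar(labels)]))
}
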