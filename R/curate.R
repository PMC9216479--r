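#' Run the per-record curation gates
#'
#' Applies the fixed stage sequence — length, six-frame translation +
#' profile-HMM search, trusted cutoff, ENA annotation consistency,
#' contamination screen, internal-N filter (after terminal-N trimming)
#' and stop-codon check — to every record, recording an ordered audit
#' trail per record. Stages after the first failure are marked
#' `"skip"`; every gate is a pure predicate, so the outcome (though not
#' the audit trail) is order-independent. Kept records carry their
#' trimmed sequence and winning hit.
#'
#' @param records list of `coi_record` (ENA and/or BOLD).
#' @param profile a `coi_profile`.
#' @param store a `coi_taxstore` (mitochondrial code lookup; its
#'   `acc2taxid` field, when set, resolves ENA taxids).
#' @param cfg a [filter_config()].
#' @param blast_hits parsed hits from [read_blast_tab()], or `NULL` to
#'   skip the contamination stage.
#' @return `list(decisions, records, synonym_overlaps)`: `decisions` is a
#'   data.frame (`record_id`, `source`, `kept`, `stage`, `reason`) where
#'   `stage` is the first failing stage (`NA` when kept); `records` the
#'   kept records (sequence trimmed, `$hit` attached); `synonym_overlaps`
#'   the COI-consistent overlap results of kept ENA records for
#'   [harvest_synonyms()].
#' @export
curate_records <- function(records, profile, store, cfg = filter_config(),
                           blast_hits = NULL) {
  decisions <- vector("list", length(records))
  kept <- list()
  syn <- list()
  trail_all <- vector("list", length(records))

  for (i in seq_along(records)) {
    rec <- records[[i]]
    trail <- data.frame(stage = COI_STAGES, status = "skip", detail = "",
                        stringsAsFactors = FALSE)
    set <- function(stage, status, detail = "") {
      trail[trail$stage == stage, c("status", "detail")] <<-
        list(status, detail)
    }
    fail_stage <- NA_character_
    fail_reason <- NA_character_

    repeat {
      # length
      if (!length_gate(rec, cfg)) {
        set("length", "fail", sprintf("%d nt outside [%d, %d]",
                                      nchar(rec$sequence), cfg$min_len,
                                      cfg$max_len))
        fail_stage <- "length"
        fail_reason <- trail$detail[trail$stage == "length"]
        break
      }
      set("length", "pass", sprintf("%d nt", nchar(rec$sequence)))

      # translation + profile search
      taxid <- record_taxid(rec, store)
      code <- mito_code_for(taxid, store)
      if (nchar(rec$sequence) < 3L) {
        set("hmm", "fail", "sequence shorter than one codon")
        fail_stage <- "hmm"; fail_reason <- "sequence shorter than one codon"
        break
      }
      frames <- six_frame_translate(rec$sequence, code)
      hit <- best_frame_hit(profile, frames, nchar(rec$sequence))
      if (is.null(hit)) {
        set("hmm", "fail", "no scorable frame")
        fail_stage <- "hmm"; fail_reason <- "no scorable frame"
        break
      }
      set("hmm", "pass", sprintf("frame %s, %.2f bits", hit$frame,
                                 hit$score_bits))
      rec$hit <- hit
      rec$mito_code <- attr(code, "code_id")

      # trusted cutoff
      if (!passes_tc(hit, profile, cfg$tc_override)) {
        d <- sprintf("%.2f bits < TC %.2f", hit$score_bits,
                     cfg$tc_override %||% profile$tc)
        set("tc", "fail", d)
        fail_stage <- "tc"; fail_reason <- d
        break
      }
      set("tc", "pass", sprintf("%.2f bits", hit$score_bits))

      # ENA annotation consistency (BOLD entries are pre-curated upstream)
      if (rec$source == "ENA") {
        val <- validate_ena_record(rec, hit, cfg)
        if (val$verdict == "reject") {
          set("annotation", "fail", val$reason)
          fail_stage <- "annotation"; fail_reason <- val$reason
          break
        }
        set("annotation", "pass", val$reason)
        rec$qualifying_overlaps <- val$qualifying
      } else {
        set("annotation", "pass", "not applicable (no feature table)")
      }

      # contamination screen
      if (is.null(blast_hits)) {
        set("contamination", "skip", "no similarity results supplied")
      } else if (!contamination_gate(rec$record_id, blast_hits, store)) {
        set("contamination", "fail", "best hit in a rejected clade")
        fail_stage <- "contamination"
        fail_reason <- "best hit in a rejected clade"
        break
      } else {
        set("contamination", "pass", "")
      }

      # terminal-N trim + internal-N cap; the trimmed sequence is final
      tr <- trim_terminal_n(rec$sequence)
      if (!nzchar(tr$sequence)) {
        set("n_filter", "fail", "empty after trim")
        fail_stage <- "n_filter"; fail_reason <- "empty after trim"
        break
      }
      if (!internal_n_gate(tr$sequence, cfg)) {
        d <- sprintf("more than %d internal N", cfg$max_internal_n)
        set("n_filter", "fail", d)
        fail_stage <- "n_filter"; fail_reason <- d
        break
      }
      set("n_filter", "pass",
          sprintf("trimmed %d+%d terminal N", tr$n_leading, tr$n_trailing))

      # stop codons within the accepted envelope
      if (!stop_codon_gate(hit, cfg)) {
        set("stop_codon", "fail", "internal stop codon in envelope")
        fail_stage <- "stop_codon"
        fail_reason <- "internal stop codon in envelope"
        break
      }
      set("stop_codon", "pass", "")

      rec$sequence <- tr$sequence
      break
    }

    is_kept <- is.na(fail_stage)
    decisions[[i]] <- data.frame(record_id = rec$record_id,
                                 source = rec$source, kept = is_kept,
                                 stage = fail_stage, reason = fail_reason,
                                 stringsAsFactors = FALSE)
    trail_all[[i]] <- cbind(record_id = rec$record_id, trail)
    if (is_kept) {
      kept[[length(kept) + 1L]] <- rec
      if (rec$source == "ENA" && length(rec$qualifying_overlaps)) {
        syn <- c(syn, rec$qualifying_overlaps)
      }
    }
  }

  list(decisions = do.call(rbind, decisions),
       trail = do.call(rbind, trail_all),
       records = kept, synonym_overlaps = syn)
}

# Taxid used for genetic-code lookup and lineage resolution:
# ENA accession via acc2taxid, else the flat file's taxon db_xref hint,
# else (BOLD) the lowest-rank raw name found in the store.
record_taxid <- function(rec, store) {
  if (!is.na(rec$accession %||% NA) &&
      rec$accession %in% names(store$acc2taxid)) {
    return(store$acc2taxid[[rec$accession]])
  }
  hint <- rec$taxon$taxid_hint %||% NA_integer_
  if (!is.na(hint) && as.character(hint) %in% names(store$parent)) {
    return(as.integer(hint))
  }
  ranks <- rec$taxon$ranks
  if (!is.null(ranks)) {
    for (r in rev(COI_RANKS)) {
      nm <- ranks[[r]]
      if (!is.na(nm %||% NA)) {
        cand <- store$name2tax[[tolower(nm)]]
        if (length(cand) == 1L) return(cand)
        if (length(cand) > 1L) {
          picked <- resolve_homonym(cand, ranks, store, query = nm)
          if (!is.na(picked)) return(picked)
        }
      }
    }
  }
  NA_integer_
}
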