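#' Local Viterbi alignment of a peptide against a profile HMM
#'
#' Plan7-lite local alignment in bit space: begin/end connect to every
#' match state with uniform zero-bit local entry/exit, and the optimal
#' path over match/insert/delete states is found by Viterbi. Unknown
#' residues (`X`, `*`, anything outside the 20-letter alphabet) emit
#' background, i.e. contribute 0 bits. This is the gate's score; it has no
#' MSV/forward stages or E-values (an external `hmmsearch` backend can be
#' substituted via [read_domtbl()]).
#'
#' @param profile a `coi_profile`.
#' @param peptide amino-acid string (may contain `*`/`X`).
#' @return `list(score_bits, aa_start, aa_end)` with a 0-based half-open
#'   peptide envelope; an empty peptide scores `-Inf` with no envelope.
#' @export
viterbi_local <- function(profile, peptide) {
  if (is.na(peptide) || !nzchar(peptide)) {
    return(list(score_bits = -Inf, aa_start = NA_integer_,
                aa_end = NA_integer_))
  }
  res <- strsplit(toupper(peptide), "")[[1]]
  idx <- match(res, AA20) - 1L
  idx[is.na(idx)] <- -1L
  v <- viterbi_local_cpp(profile$match_bits, profile$trans_bits, idx)
  list(score_bits = v$score, aa_start = v$aa_start, aa_end = v$aa_end)
}

#' Best-scoring frame across six translated frames
#'
#' Scores every frame with [viterbi_local()] and keeps the maximum; ties
#' break by frame order (+1, +2, +3, -1, -2, -3). The winning peptide
#' envelope maps back to 0-based half-open coordinates on the forward
#' nucleotide sequence: forward frames as `o + 3*aa`, reverse frames by
#' reflection through the sequence length.
#'
#' @param profile a `coi_profile`.
#' @param frames list of six frames from [six_frame_translate()].
#' @param seq_len nucleotide length of the original sequence.
#' @return a `coi_hit` (`frame`, `score_bits`, `aa_start`, `aa_end`,
#'   `nt_start`, `nt_end`, `peptide`) or `NULL` when every frame scores
#'   `-Inf`.
#' @export
best_frame_hit <- function(profile, frames, seq_len) {
  best <- NULL
  for (f in frames) {
    v <- viterbi_local(profile, f$peptide)
    if (is.finite(v$score_bits) &&
        (is.null(best) || v$score_bits > best$score_bits)) {
      best <- c(v, list(frame = f$frame, offset = f$offset,
                        peptide = f$peptide))
    }
  }
  if (is.null(best)) return(NULL)
  o <- best$offset
  if (startsWith(best$frame, "+")) {
    nt <- c(o + 3L * best$aa_start, o + 3L * best$aa_end)
  } else {
    nt <- c(seq_len - (o + 3L * best$aa_end),
            seq_len - (o + 3L * best$aa_start))
  }
  structure(list(frame = best$frame, score_bits = best$score_bits,
                 aa_start = best$aa_start, aa_end = best$aa_end,
                 nt_start = nt[1], nt_end = nt[2], peptide = best$peptide),
            class = "coi_hit")
}

#' Trusted-cutoff gate
#'
#' Accepts a hit whose bit score reaches the profile's trusted cutoff
#' (TC), the lowest score of any known true member of the family; the
#' comparison is inclusive, matching HMMER's `--cut_tc` semantics.
#'
#' @param hit a `coi_hit`.
#' @param profile a `coi_profile`; `tc_override` replaces its TC.
#' @param tc_override optional numeric threshold (required when the
#'   profile carries no TC line).
#' @return `TRUE`/`FALSE`.
#' @export
passes_tc <- function(hit, profile, tc_override = NULL) {
  tc <- tc_override %||% profile$tc
  if (is.na(tc)) {
    stop("profile has no TC cutoff; supply tc_override (gate_mode manual)")
  }
  isTRUE(hit$score_bits >= tc)
}

#' Parse hmmsearch per-domain tabular output
#'
#' Reads the `--domtblout` dialect of HMMER3 and keeps, for each target
#' sequence, the domain with the highest domain bit score, together with
#' its envelope coordinates (converted from 1-based inclusive to 0-based
#' half-open). The result can stand in for the built-in scorer when an
#' external hmmsearch run is preferred.
#'
#' @param path path to a domtblout file.
#' @return named list of `coi_hit`-like records keyed by target sequence
#'   name, each with `score_bits`, `aa_start`, `aa_end` (frame and
#'   nucleotide coordinates are `NA`: the external backend sees only the
#'   translated peptides).
#' @export
read_domtbl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  hits <- list()
  for (l in lines) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(f) < 21) {
      warning("malformed domtblout line skipped: ", substr(l, 1, 60))
      next
    }
    score <- suppressWarnings(as.numeric(f[14]))
    env_from <- suppressWarnings(as.integer(f[20]))
    env_to <- suppressWarnings(as.integer(f[21]))
    if (is.na(score) || is.na(env_from) || is.na(env_to)) {
      warning("malformed domtblout line skipped: ", substr(l, 1, 60))
      next
    }
    id <- f[1]
    if (is.null(hits[[id]]) || score > hits[[id]]$score_bits) {
      hits[[id]] <- structure(
        list(frame = NA_character_, score_bits = score,
             aa_start = env_from - 1L, aa_end = env_to,
             nt_start = NA_integer_, nt_end = NA_integer_,
             peptide = NA_character_),
        class = "coi_hit")
    }
  }
  hits
}
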