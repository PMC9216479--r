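#' Construct a genetic code table
#'
#' A genetic code maps each of the 64 codons to an amino acid (`*` for
#' stop). Codes are usually taken from a parsed `gencode.dmp`
#' (see [read_taxdump()]); this constructor also builds the standard NCBI
#' tables by id via [Biostrings::getGeneticCode()].
#'
#' @param id NCBI translation-table integer (e.g. 1 standard, 2 vertebrate
#'   mitochondrial, 5 invertebrate mitochondrial).
#' @param codon_to_aa optional named character vector of 64 codons to
#'   single-letter amino acids; when `NULL` the table is looked up in
#'   Biostrings.
#' @return object of class `coi_gencode`: named character vector of 64
#'   codon translations with attribute `code_id`.
#' @examples
#' gc5 <- genetic_code(5)
#' unname(gc5[["AGA"]])  # serine under the invertebrate mitochondrial code
#' @export
genetic_code <- function(id, codon_to_aa = NULL) {
  if (is.null(codon_to_aa)) {
    codon_to_aa <- Biostrings::getGeneticCode(as.character(id))
  }
  codon_to_aa <- toupper(codon_to_aa)
  names(codon_to_aa) <- toupper(names(codon_to_aa))
  stopifnot(length(codon_to_aa) == 64L, any(codon_to_aa == "*"))
  structure(codon_to_aa, code_id = as.integer(id), class = "coi_gencode")
}

# Build a genetic code from a gencode.dmp `cde` field: 64 amino acids in
# TCAG x TCAG x TCAG codon order.
genetic_code_from_cde <- function(id, cde) {
  cde <- gsub("\\s", "", cde)
  stopifnot(nchar(cde) == 64L)
  b <- c("T", "C", "A", "G")
  i <- 0:63
  codons <- paste0(b[i %/% 16L + 1L], b[(i %/% 4L) %% 4L + 1L], b[i %% 4L + 1L])
  genetic_code(id, setNames(strsplit(cde, "")[[1]], codons))
}

#' Mitochondrial genetic code for a taxid
#'
#' Resolves the mitochondrial translation table of a taxon by
#' nearest-ancestor lookup over the taxonomy store's mitochondrial
#' genetic-code field (0 means "unset, inherit"). Unresolved taxids fall
#' back to a configured default, table 5 (invertebrate mitochondrial),
#' reflecting the dominance of Arthropoda among animal barcode records.
#'
#' @param taxid integer taxid, or `NA` for unresolved.
#' @param store a taxonomy store from [read_taxdump()].
#' @param default translation-table id used when no ancestor carries one.
#' @return a `coi_gencode` (from the store's parsed `gencode.dmp` tables
#'   when available, else the built-in table).
#' @export
mito_code_for <- function(taxid, store, default = 5L) {
  code_id <- default
  if (!is.na(taxid)) {
    t <- as.character(taxid)
    seen <- character()
    while (t %in% names(store$parent) && !(t %in% seen)) {
      m <- store$mgc[[t]] %||% 0L
      if (!is.na(m) && m > 0L) {
        code_id <- m
        break
      }
      seen <- c(seen, t)
      p <- as.character(store$parent[[t]])
      if (identical(p, t)) break
      t <- p
    }
  }
  store$gencodes[[as.character(code_id)]] %||% genetic_code(code_id)
}

#' Reverse complement of a DNA string
#'
#' IUPAC-aware, pure string operation ('N' and ambiguity codes map to
#' their complements; unknown characters are left as-is).
#'
#' @param x single DNA string.
#' @return reverse-complemented string.
#' @export
reverse_complement <- function(x) {
  x <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
              "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  paste(rev(strsplit(x, "")[[1]]), collapse = "")
}

translate_frame <- function(seq, offset, code) {
  L <- nchar(seq)
  n <- (L - offset) %/% 3L
  if (n <= 0L) return("")
  starts <- offset + 1L + 3L * (0:(n - 1L))
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"  # any codon with a non-ACGT base
  paste(aa, collapse = "")
}

#' Six-frame conceptual translation
#'
#' Translates a nucleotide sequence in all six reading frames under one
#' genetic code. Translation runs through stop codons (rendered `*`); the
#' profile search localizes the coding region afterwards, and the
#' stop-codon gate inspects the selected envelope. Codons containing any
#' non-ACGT symbol translate to `X`.
#'
#' @param sequence uppercase DNA string.
#' @param code a `coi_gencode`.
#' @return list of six frames, each `list(frame, offset, peptide)` with
#'   frame labels `+1,+2,+3,-1,-2,-3`; offsets 0-2 apply to the forward
#'   sequence (plus frames) or its reverse complement (minus frames).
#'   Sequences shorter than one codon yield empty peptides.
#' @export
six_frame_translate <- function(sequence, code) {
  sequence <- toupper(sequence)
  rc <- reverse_complement(sequence)
  frames <- list()
  labs <- c("+1", "+2", "+3", "-1", "-2", "-3")
  for (i in 0:2) {
    frames[[i + 1L]] <- list(frame = labs[i + 1L], offset = i,
                             peptide = translate_frame(sequence, i, code))
  }
  for (i in 0:2) {
    frames[[i + 4L]] <- list(frame = labs[i + 4L], offset = i,
                             peptide = translate_frame(rc, i, code))
  }
  frames
}
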