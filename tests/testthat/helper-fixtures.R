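# In-code builders for tiny test inputs (everything generated at test
# time; nothing binary or stored).

# small taxdump on disk: Metazoa -> Arthropoda -> Insecta -> Lepidoptera
# -> Nymphalidae -> Vanessa -> Vanessa atalanta, plus Bacteria/Archaea/
# Viridiplantae roots and a chordate branch with its own mito code.
write_test_taxdump <- function(dir = tempfile("taxdump")) {
  dir.create(dir, showWarnings = FALSE)
  row <- function(...) paste(paste(c(...), collapse = "\t|\t"), "|",
                             sep = "\t")
  nodes <- list(
    c(1, 1, "no rank", 0), c(131567, 1, "no rank", 0),
    c(2, 131567, "superkingdom", 0), c(2157, 131567, "superkingdom", 0),
    c(2759, 131567, "superkingdom", 0),
    c(33090, 2759, "kingdom", 0), c(33208, 2759, "kingdom", 5),
    c(6656, 33208, "phylum", 0), c(50557, 6656, "class", 0),
    c(7088, 50557, "order", 0), c(33415, 7088, "family", 0),
    c(42275, 33415, "genus", 0), c(42276, 42275, "species", 0),
    c(7711, 33208, "phylum", 2),          # chordate-like branch, table 2
    c(99001, 7711, "class", 0), c(99002, 99001, "species", 0),
    c(561, 2, "species", 0))
  names_ <- list(
    c(1, "root"), c(131567, "cellular organisms"), c(2, "Bacteria"),
    c(2157, "Archaea"), c(2759, "Eukaryota"), c(33090, "Viridiplantae"),
    c(33208, "Metazoa"), c(6656, "Arthropoda"), c(50557, "Insecta"),
    c(7088, "Lepidoptera"), c(33415, "Nymphalidae"), c(42275, "Vanessa"),
    c(42276, "Vanessa atalanta"), c(7711, "Chordata"),
    c(99001, "Actinopteri"), c(99002, "Fishus testus"),
    c(561, "Escherichia testi"))
  writeLines(vapply(nodes, function(n)
    row(n[1], n[2], n[3], "", 0, 0, 1, 0, n[4], 0), character(1)),
    file.path(dir, "nodes.dmp"))
  nl <- vapply(names_, function(n) row(n[1], n[2], "", "scientific name"),
               character(1))
  nl <- c(nl, row(42276, "Pyrameis atalanta", "", "synonym"))
  writeLines(nl, file.path(dir, "names.dmp"))
  cde <- function(id) {
    code <- Biostrings::getGeneticCode(as.character(id))
    b <- c("T", "C", "A", "G")
    i <- 0:63
    paste(unname(code[paste0(b[i %/% 16 + 1], b[(i %/% 4) %% 4 + 1],
                             b[i %% 4 + 1])]), collapse = "")
  }
  writeLines(vapply(c(1, 2, 5), function(id)
    row(id, "", paste("table", id), cde(id), ""), character(1)),
    file.path(dir, "gencode.dmp"))
  dir
}

test_store <- function() {
  s <- read_taxdump(write_test_taxdump())
  s$acc2taxid <- c(TACC001 = 42276L, TACC002 = 99002L)
  s
}

# a profile whose consensus is `cons`, written/parsed through the toy
# HMMER3/f writer (TC = 34 unless overridden)
test_profile <- function(cons = coiref:::toy_consensus(), tc = 34) {
  f <- tempfile(fileext = ".hmm")
  coiref:::write_toy_hmm(f, cons, tc)
  read_hmm_profile(f)
}

# minimal EMBL entry text
embl_entry <- function(acc, seqnt, ft_lines = character()) {
  L <- nchar(seqnt)
  seq_lines <- substring(seqnt, seq(1, L, 60), pmin(seq(1, L, 60) + 59, L))
  c(sprintf("ID   %s; SV 1; linear; genomic DNA; STD; INV; %d BP.", acc, L),
    sprintf("AC   %s;", acc),
    "OS   Vanessa atalanta",
    ft_lines,
    sprintf("SQ   Sequence %d BP;", L),
    paste0("     ", tolower(seq_lines)),
    "//")
}

write_embl <- function(..., file = tempfile(fileext = ".dat")) {
  writeLines(unlist(list(...)), file)
  file
}

fake_hit <- function(score, aa_start = 0L, aa_end = 10L, nt_start = 0L,
                     nt_end = 30L, frame = "+1", peptide = NA_character_) {
  structure(list(frame = frame, score_bits = score, aa_start = aa_start,
                 aa_end = aa_end, nt_start = nt_start, nt_end = nt_end,
                 peptide = peptide), class = "coi_hit")
}

fake_cds <- function(spans, pseudo = FALSE, gene = NA_character_,
                     product = NA_character_) {
  structure(list(key = "CDS", spans = spans, strand = "+", gene = gene,
                 product = product, pseudo = pseudo), class = "coi_cds")
}
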