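# Synthetic-corpus generator: writes miniature EMBL flat files, BOLD TSV,
# taxdump, accession2taxid, a toy HMMER3/f profile and a BLAST tabular
# file, together with a ground-truth manifest of expected per-record
# verdicts and summary counts. Everything is determined by (seed, params).

# The toy profile's consensus: 219 residues (-> 657 coding nt, 658 bp
# records, the standard animal barcode length) cycling through a
# 14-letter alphabet that deliberately excludes P, L, S, G, E and R: the
# spacer codon CCT reads as P/L/S on the forward frames and R/G/E on the
# reverse frames of its repeats, so spacer DNA can never extend a match.
toy_consensus <- function(M = 219L) {
  alpha <- c("A", "C", "D", "F", "H", "I", "K", "M", "N", "Q", "T", "V",
             "W", "Y")
  paste(alpha[(5L * (seq_len(M) - 1L)) %% 14L + 1L], collapse = "")
}

# Emission model of the toy profile: consensus residue 0.6, the rest
# uniform; background uniform 1/20. One consensus match is worth
# log2(0.6*20) = 3.585 bits, so with TC = 34 a run of 10 consensus codons
# passes (35.2 bits) and a run of 9 fails (31.7 bits) by construction.
TOY_P_CONS <- 0.6
TOY_TC <- 34

write_toy_hmm <- function(path, consensus = toy_consensus(), tc = TOY_TC) {
  M <- nchar(consensus)
  res <- strsplit(consensus, "")[[1]]
  p_other <- (1 - TOY_P_CONS) / 19
  fmt <- function(x) formatC(x, digits = 5, format = "f", width = 8)
  bg_line <- paste(fmt(rep(log(20), 20)), collapse = " ")
  t_line <- paste(fmt(-log(c(0.95, 0.025, 0.025, 0.9, 0.1, 0.85, 0.15))),
                  collapse = " ")
  lines <- c(
    "HMMER3/f [3.4 | toy]",
    "NAME  COI_toy",
    sprintf("LENG  %d", M),
    "ALPH  amino",
    "RF    no",
    "MM    no",
    "CONS  yes",
    "CS    no",
    "MAP   yes",
    sprintf("GA    %.2f %.2f;", tc - 9, tc - 9),
    sprintf("TC    %.2f %.2f;", tc, tc),
    sprintf("NC    %.2f %.2f;", tc - 14, tc - 14),
    paste0("HMM     ", paste(sprintf("%8s", AA20), collapse = " ")),
    paste0("        ", paste(sprintf("%8s", c("m->m", "m->i", "m->d", "i->m",
                                              "i->i", "d->m", "d->d")),
                             collapse = " ")),
    paste0("  COMPO ", bg_line),
    paste0("        ", bg_line),
    paste0("        ", t_line))
  for (k in seq_len(M)) {
    p <- rep(p_other, 20)
    p[match(res[k], AA20)] <- TOY_P_CONS
    lines <- c(lines,
               sprintf("%7d %s %6d %s - - -", k,
                       paste(fmt(-log(p)), collapse = " "), k, res[k]),
               paste0("        ", bg_line),
               paste0("        ", t_line))
  }
  writeLines(c(lines, "//"), path)
  invisible(path)
}

# deterministic reverse translation: lexicographically smallest codon
codons_for <- function(aa_string, code) {
  aa <- strsplit(aa_string, "")[[1]]
  pick <- vapply(aa, function(a) {
    cands <- sort(names(code)[code == a])
    if (!length(cands)) stop("no codon for residue ", a)
    cands[1]
  }, character(1))
  paste(pick, collapse = "")
}

# ---- taxonomy fixture -------------------------------------------------

toy_tax_tree <- function(n_families = 3L, genera_per_family = 2L,
                         species_per_genus = 2L) {
  nodes <- data.frame(
    taxid = c(1L, 131567L, 2L, 2157L, 2759L, 33090L, 33208L, 6656L,
              50557L, 7088L),
    parent = c(1L, 1L, 131567L, 131567L, 131567L, 2759L, 2759L, 33208L,
               6656L, 50557L),
    rank = c("no rank", "no rank", "superkingdom", "superkingdom",
             "superkingdom", "kingdom", "kingdom", "phylum", "class",
             "order"),
    name = c("root", "cellular organisms", "Bacteria", "Archaea",
             "Eukaryota", "Viridiplantae", "Metazoa", "Arthropoda",
             "Insecta", "Lepidoptera"),
    mgc = c(0L, 0L, 0L, 0L, 0L, 0L, 5L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)

  species <- data.frame(taxid = integer(), name = character(),
                        genus = character(), family = character(),
                        stringsAsFactors = FALSE)
  epithets <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta")
  g <- 0L
  for (f in seq_len(n_families)) {
    fam_id <- 810000L + f
    fam_name <- sprintf("Famfixidae%02d", f)
    nodes <- rbind(nodes, data.frame(taxid = fam_id, parent = 7088L,
                                     rank = "family", name = fam_name,
                                     mgc = 0L))
    for (gg in seq_len(genera_per_family)) {
      g <- g + 1L
      gen_id <- 910000L + g
      gen_name <- sprintf("Fixigenus%02d", g)
      nodes <- rbind(nodes, data.frame(taxid = gen_id, parent = fam_id,
                                       rank = "genus", name = gen_name,
                                       mgc = 0L))
      for (s in seq_len(species_per_genus)) {
        sp_id <- 1000000L + 10L * g + s
        sp_name <- paste(gen_name, epithets[s])
        nodes <- rbind(nodes, data.frame(taxid = sp_id, parent = gen_id,
                                         rank = "species", name = sp_name,
                                         mgc = 0L))
        species <- rbind(species, data.frame(
          taxid = sp_id, name = sp_name, genus = gen_name,
          family = fam_name, stringsAsFactors = FALSE))
      }
    }
  }
  # a bacterial species as contamination BLAST subject
  nodes <- rbind(nodes, data.frame(taxid = 1100001L, parent = 2L,
                                   rank = "species", name = "Badbug fixus",
                                   mgc = 0L))
  list(nodes = nodes, species = species)
}

write_taxdump_fixture <- function(dir, tree) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nd <- tree$nodes
  dmp_row <- function(...) paste(paste(c(...), collapse = "\t|\t"), "|",
                                 sep = "\t")
  writeLines(vapply(seq_len(nrow(nd)), function(i) {
    dmp_row(nd$taxid[i], nd$parent[i], nd$rank[i], "", 0, 0, 1, 0,
            nd$mgc[i], 0, 0, 0, "")
  }, character(1)), file.path(dir, "nodes.dmp"))

  name_lines <- vapply(seq_len(nrow(nd)), function(i) {
    dmp_row(nd$taxid[i], nd$name[i], "", "scientific name")
  }, character(1))
  # one synonym-class row that must stay out of the name index
  name_lines <- c(name_lines,
                  dmp_row(tree$species$taxid[1], "Synonymus vetus", "",
                          "synonym"))
  writeLines(name_lines, file.path(dir, "names.dmp"))

  cde <- function(id) {
    code <- Biostrings::getGeneticCode(as.character(id))
    b <- c("T", "C", "A", "G")
    i <- 0:63
    codons <- paste0(b[i %/% 16L + 1L], b[(i %/% 4L) %% 4L + 1L],
                     b[i %% 4L + 1L])
    paste(unname(code[codons]), collapse = "")
  }
  writeLines(vapply(c(1L, 2L, 5L), function(id) {
    dmp_row(id, "", paste("table", id), cde(id), "")
  }, character(1)), file.path(dir, "gencode.dmp"))
  invisible(dir)
}

# ---- corpus records ---------------------------------------------------

ENA_VIOLATIONS <- c("too_long", "cds_overlap_79", "pseudogene",
                    "bacterial_hit", "internal_stop")
BOLD_VIOLATIONS <- c("too_short", "low_hmm", "internal_n6",
                     "unknown_taxon", "changed_name")

VERDICTS <- list(
  clean = c("keep", NA), mini_barcode = c("keep", NA),
  terminal_n = c("keep", NA),
  unknown_taxon = c("keep", NA), changed_name = c("keep", NA),
  too_short = c("reject", "length"), too_long = c("reject", "length"),
  low_hmm = c("reject", "tc"),
  cds_overlap_79 = c("reject", "annotation"),
  pseudogene = c("reject", "annotation"),
  bacterial_hit = c("reject", "contamination"),
  internal_n6 = c("reject", "n_filter"),
  internal_stop = c("reject", "stop_codon"))

make_sequence <- function(class, code) {
  cons <- toy_consensus()
  clean <- paste0(codons_for(cons, code), "T")  # 658 nt
  switch(class,
    clean = clean,
    terminal_n = paste0("NNN", clean, "NN"),
    mini_barcode = paste0(codons_for(substr(cons, 1, 133), code), "T"),  # 400
    unknown_taxon = clean,
    changed_name = clean,
    bacterial_hit = clean,
    pseudogene = clean,
    too_short = substr(clean, 1, 50),
    too_long = strrep("CCT", 20001L),            # 60003 nt
    low_hmm = paste0(codons_for(substr(cons, 1, 9), code),
                     strrep("CCT", 210L), "T"),  # 9 consensus codons only
    internal_n6 = {
      s <- clean
      for (cd in c(50L, 52L, 54L, 56L, 58L, 60L)) {
        substr(s, 3L * (cd - 1L) + 1L, 3L * (cd - 1L) + 1L) <- "N"
      }
      s
    },
    internal_stop = {
      s <- clean
      substr(s, 328L, 330L) <- "TAA"             # codon 110 -> stop
      s
    },
    cds_overlap_79 = paste0(strrep("CCT", 40L), "C",
                            codons_for(substr(cons, 1, 193), code),
                            strrep("CCT", 20L)),  # footprint [121,700) vs CDS [0,600)
    stop("unknown violation class: ", class))
}

expected_length <- function(class) {
  switch(class, clean = 658L, unknown_taxon = 658L, changed_name = 658L,
         terminal_n = 658L, mini_barcode = 400L, NA_integer_)
}

ena_cds_labels <- list(list(gene = "COI", product = NA),
                       list(gene = "COX1", product = NA),
                       list(gene = NA,
                            product = "cytochrome c oxidase subunit I"),
                       list(gene = "CO1",
                            product = "cytochrome oxidase subunit 1"))

#' Generate a deterministic synthetic curation corpus
#'
#' Writes a miniature input set in the exact dialects the readers expect —
#' an EMBL flat file, a BOLD-style TSV, a toy HMMER3/f COI-like profile
#' (TC = 34), NCBI-style taxdump files, an accession2taxid mapping and a
#' BLAST tabular file — and returns a manifest of ground-truth
#' expectations: the per-record verdict and failing stage, provenance
#' counts, the synonym list, the taxonomy-update count and distinct-taxon
#' counts. Clean records are 658 bp reverse-translated copies of the
#' profile consensus (a third of the clean BOLD-only records are 400 bp
#' mini-barcodes); each violation class is planted in at least one record
#' with geometry that decides its verdict by construction (e.g. the CDS
#' overlap violation plants 479 shared sites over a 600-site CDS).
#' Regenerating with the same seed and parameters reproduces the corpus
#' byte-identically.
#'
#' @param dir output directory (created).
#' @param seed integer seed controlling species assignment and metadata.
#' @param n_ena,n_bold record counts per source.
#' @param overlap_fraction fraction of records shared between sources
#'   (shared accessions, all clean).
#' @param violations character vector of violation classes to plant, one
#'   record each (default: every supported class). More classes than
#'   available exclusive records is an error.
#' @return a `coi_manifest` list: `records` (data.frame with `record_id`,
#'   `source`, `class`, `verdict`, `stage`, `final_length`), `provenance`,
#'   `synonyms`, `n_updated`, `mode_length`, `distinct`, `files`, `seed`,
#'   `params`.
#' @export
generate_corpus <- function(dir, seed = 1L, n_ena = 20L, n_bold = 20L,
                            overlap_fraction = 0.5,
                            violations = c(ENA_VIOLATIONS,
                                           BOLD_VIOLATIONS)) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(seed)

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_shared <- round(overlap_fraction * min(n_ena, n_bold))
  ena_v <- intersect(violations, ENA_VIOLATIONS)
  bold_v <- intersect(violations, BOLD_VIOLATIONS)
  if (n_shared + length(ena_v) > n_ena ||
      n_shared + length(bold_v) > n_bold) {
    stop("more violation classes than available exclusive records")
  }

  tree <- toy_tax_tree()
  write_taxdump_fixture(file.path(dir, "taxdump"), tree)
  write_toy_hmm(file.path(dir, "profile.hmm"))
  code5 <- genetic_code(5)

  sp_pool <- tree$species
  pick_species <- function(n) {
    sp_pool[sample.int(nrow(sp_pool), n, replace = TRUE), , drop = FALSE]
  }

  # --- plan records ---
  plan <- list()
  add <- function(source, idx, class, shared_with = NA_character_) {
    acc <- if (source == "ENA" || !is.na(shared_with))
      shared_with %||% sprintf("ACC%05d", idx) else NA_character_
    pid <- if (source == "BOLD") sprintf("FIX%03d-21", idx) else NA_character_
    plan[[length(plan) + 1L]] <<- list(source = source, idx = idx,
                                       class = class, accession = acc,
                                       process_id = pid)
  }
  for (i in seq_len(n_ena)) {
    class <- if (i <= n_shared) "clean"
    else if (i - n_shared <= length(ena_v)) ena_v[i - n_shared]
    else "clean"
    add("ENA", i, class)
  }
  n_clean_bold_only <- 0L
  for (i in seq_len(n_bold)) {
    if (i <= n_shared) {
      add("BOLD", i, "clean", shared_with = sprintf("ACC%05d", i))
    } else if (i - n_shared <= length(bold_v)) {
      add("BOLD", i, bold_v[i - n_shared])
    } else {
      n_clean_bold_only <- n_clean_bold_only + 1L
      class <- if (n_clean_bold_only == 1L) "terminal_n"
      else if (n_clean_bold_only %% 3L == 0L) "mini_barcode" else "clean"
      add("BOLD", i, class)
    }
  }

  sp <- pick_species(length(plan))
  for (i in seq_along(plan)) plan[[i]]$species <- sp[i, ]
  # shared pairs must agree on the species (same specimen, two archives)
  by_acc <- split(seq_along(plan),
                  vapply(plan, function(p) p$accession %||% "", character(1)))
  for (acc in names(by_acc)) {
    if (nzchar(acc) && length(by_acc[[acc]]) > 1L) {
      first <- by_acc[[acc]][1]
      for (j in by_acc[[acc]][-1]) plan[[j]]$species <- plan[[first]]$species
    }
  }

  countries <- c("Italy: Apulia", "France: Brittany", "Spain")
  dates <- c("12-Jul-2019", "2018", "03-Mar-2020")

  # --- EMBL flat file ---
  embl <- character()
  label_i <- 0L
  ena_plans <- Filter(function(p) p$source == "ENA", plan)
  for (p in ena_plans) {
    seqnt <- make_sequence(p$class, code5)
    L <- nchar(seqnt)
    lab <- ena_cds_labels[[label_i %% length(ena_cds_labels) + 1L]]
    label_i <- label_i + 1L
    ft <- c(sprintf("FT   source          1..%d", L),
            sprintf('FT                   /organism="%s"', p$species$name),
            sprintf('FT                   /db_xref="taxon:%d"',
                    p$species$taxid),
            sprintf('FT                   /country="%s"',
                    countries[p$idx %% 3L + 1L]),
            sprintf('FT                   /lat_lon="%.2f N %.2f E"',
                    round(runif(1, 35, 55), 2), round(runif(1, 5, 15), 2)),
            sprintf('FT                   /collection_date="%s"',
                    dates[p$idx %% 3L + 1L]))
    if (p$idx %% 4L == 0L) {
      ft <- c(ft, 'FT                   /host="Apis mellifera"')
    }
    cds_end <- if (p$class == "cds_overlap_79") 600L else min(657L, L)
    if (p$class != "too_long") {   # genome-scaffold-like entry: no COI CDS
      cds <- sprintf("FT   CDS             1..%d", cds_end)
      quals <- character()
      if (p$class == "pseudogene") {
        quals <- c('FT                   /gene="coxI-psi"',
                   "FT                   /pseudo")
      } else {
        if (!is.na(lab$gene)) {
          quals <- c(quals, sprintf('FT                   /gene="%s"',
                                    lab$gene))
        }
        if (!is.na(lab$product)) {
          quals <- c(quals, sprintf('FT                   /product="%s"',
                                    lab$product))
        }
      }
      ft <- c(ft, cds, quals)
      if (p$class != "pseudogene") {
        plan_labels <- c(lab$gene, lab$product)
        p$labels <- plan_labels[!is.na(plan_labels)]
      }
    }
    # record planned labels back (for the synonym manifest)
    plan[[which(vapply(plan, function(q)
      identical(q$source, "ENA") && q$idx == p$idx, logical(1)))]]$labels <-
      p$labels
    seq_lines <- substring(seqnt, seq(1, L, 60), pmin(seq(1, L, 60) + 59, L))
    embl <- c(embl,
              sprintf("ID   %s; SV 1; linear; genomic DNA; STD; INV; %d BP.",
                      p$accession, L),
              sprintf("AC   %s;", p$accession),
              sprintf("OS   %s", p$species$name),
              ft,
              sprintf("SQ   Sequence %d BP;", L),
              paste0("     ", tolower(seq_lines)),
              "//")
  }
  writeLines(embl, file.path(dir, "ena.dat"))

  # --- BOLD TSV ---
  cm <- bold_column_map()
  cols <- c(cm$process_id, cm$accession, cm$nucleotides, cm$marker,
            cm$phylum, cm$class, cm$order, cm$family, cm$genus, cm$species,
            cm$lat, cm$lon, cm$country, cm$region, cm$collection_date)
  bold_rows <- list()
  for (p in Filter(function(q) q$source == "BOLD", plan)) {
    seqnt <- make_sequence(p$class, code5)
    ranks <- c(phylum = "Arthropoda", class = "Insecta",
               order = "Lepidoptera", family = p$species$family,
               genus = p$species$genus, species = p$species$name)
    if (p$class == "changed_name") ranks[["family"]] <- "Oldfamilidae"
    if (p$class == "unknown_taxon") {
      ranks <- c(phylum = "Ghostophora", class = "Ghostia",
                 order = "Ghostida", family = "Ghostidae",
                 genus = "Ghostus", species = "Ghostus absens")
    }
    bold_rows[[length(bold_rows) + 1L]] <- c(
      p$process_id, p$accession %||% "", seqnt, "COI-5P", ranks,
      sprintf("%.4f", round(runif(1, -40, 60), 4)),
      sprintf("%.4f", round(runif(1, -100, 100), 4)),
      "Italy", "Apulia", "2019-07-12")
  }
  # one off-marker row that the reader must exclude
  bold_rows[[length(bold_rows) + 1L]] <- c("OFF001-21", "", "ATGCATGCATGC",
                                           "rbcL", "Streptophyta", "", "",
                                           "", "", "Planta incognita",
                                           "0", "0", "Italy", "", "2019")
  writeLines(c(paste(cols, collapse = "\t"),
               vapply(bold_rows, paste, character(1), collapse = "\t")),
             file.path(dir, "bold.tsv"))

  # --- accession2taxid ---
  a2t <- vapply(ena_plans, function(p) {
    sprintf("%s\t%s.1\t%d\t0", p$accession, p$accession, p$species$taxid)
  }, character(1))
  writeLines(c("accession\taccession.version\ttaxid\tgi", a2t),
             file.path(dir, "acc2taxid.tsv"))

  # --- BLAST tabular (std + staxids) ---
  blast <- character()
  for (p in ena_plans) {
    if (p$class == "bacterial_hit") {
      blast <- c(blast,
                 sprintf("%s\tGOODBUG1\t98.5\t600\t9\t0\t1\t600\t1\t600\t1e-150\t200\t%d",
                         p$accession, p$species$taxid),
                 sprintf("%s\tBADBUG1\t99.2\t650\t5\t0\t1\t650\t1\t650\t1e-170\t500\t%d",
                         p$accession, 1100001L))
    } else if (p$class == "clean" && p$idx %% 2L == 0L) {
      blast <- c(blast,
                 sprintf("%s\tGOODBUG1\t97.1\t650\t19\t0\t1\t650\t1\t650\t1e-160\t450\t%d",
                         p$accession, p$species$taxid))
    }
  }
  writeLines(blast, file.path(dir, "blast.tsv"))

  # --- manifest ---
  rec <- do.call(rbind, lapply(plan, function(p) {
    v <- VERDICTS[[p$class]]
    data.frame(record_id = if (!is.na(p$accession)) p$accession else
                 p$process_id,
               source = p$source, class = p$class, verdict = v[1],
               stage = v[2], final_length = expected_length(p$class),
               species = p$species$name, stringsAsFactors = FALSE)
  }))

  kept <- rec[rec$verdict == "keep", ]
  kept_ena_acc <- kept$record_id[kept$source == "ENA"]
  kept_bold <- kept[kept$source == "BOLD", ]
  kept_bold_acc <- kept_bold$record_id[grepl("^ACC", kept_bold$record_id)]
  both <- intersect(kept_ena_acc, kept_bold_acc)
  provenance <- c(BOLD_unique = nrow(kept_bold) - length(both),
                  ENA_unique = length(kept_ena_acc) - length(both),
                  BOTH = length(both))
  provenance <- c(provenance, total = sum(provenance))

  syn <- sort(unique(unlist(lapply(plan, function(p) {
    if (p$source == "ENA" &&
        VERDICTS[[p$class]][1] == "keep") p$labels else NULL
  }))))

  # distinct taxa among merged (dedup by accession) kept records
  merged_ids <- unique(kept$record_id)
  merged_rows <- kept[!duplicated(kept$record_id), ]
  sp_known <- merged_rows$species[merged_rows$class != "unknown_taxon"]
  distinct <- c(
    phylum = length(unique(c("Arthropoda"[length(sp_known) > 0],
                             "Ghostophora"[any(merged_rows$class ==
                                                 "unknown_taxon")]))),
    species = length(unique(merged_rows$species)),
    genus = length(unique(c(
      sub(" .*", "", sp_known),
      "Ghostus"[any(merged_rows$class == "unknown_taxon")]))))

  lengths_kept <- merged_rows$final_length
  mode_length <- as.integer(names(sort(table(lengths_kept),
                                       decreasing = TRUE))[1])

  structure(list(
    records = rec, provenance = provenance, synonyms = syn,
    n_updated = sum(rec$class == "changed_name"),
    mode_length = mode_length, distinct = distinct,
    files = list(ena = file.path(dir, "ena.dat"),
                 bold = file.path(dir, "bold.tsv"),
                 hmm = file.path(dir, "profile.hmm"),
                 taxdump = file.path(dir, "taxdump"),
                 acc2taxid = file.path(dir, "acc2taxid.tsv"),
                 blast = file.path(dir, "blast.tsv")),
    seed = seed,
    params = list(n_ena = n_ena, n_bold = n_bold,
                  overlap_fraction = overlap_fraction,
                  violations = violations)),
    class = "coi_manifest")
}
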