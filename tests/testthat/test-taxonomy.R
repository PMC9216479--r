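test_that("lineages fill the canonical ranks from the parent walk", {
  store <- test_store()
  lin <- lineage_from_taxid(42276L, store)
  expect_equal(unname(lin$name),
               c("Metazoa", "Arthropoda", "Insecta", "Lepidoptera",
                 "Nymphalidae", "Vanessa", "Vanessa atalanta"))
  expect_equal(unname(lin$taxid[["species"]]), "42276")
  # genus-level taxid leaves species NA
  lin2 <- lineage_from_taxid(42275L, store)
  expect_equal(unname(lin2$name[["species"]]), "NA")
  expect_equal(unname(lin2$name[["genus"]]), "Vanessa")
  # absent taxid: all NA with a warning
  expect_warning(lin3 <- lineage_from_taxid(123456L, store), "absent")
  expect_true(all(lin3$name == "NA"))
  # superkingdom-and-below ranks never fill canonical slots
  expect_equal(unname(lineage_from_taxid(2L, store)$name[["kingdom"]]), "NA")
})

test_that("each filled rank is an ancestor-or-self of the query taxid", {
  store <- test_store()
  for (t in c(42276L, 42275L, 99002L)) {
    lin <- lineage_from_taxid(t, store)
    anc <- as.character(coiref:::ancestors_of(t, store))
    filled <- lin$taxid[lin$taxid != "NA"]
    expect_true(all(filled %in% anc))
  }
})

merged_bold <- function(ranks, acc = NA_character_) {
  bold <- coiref:::new_record("FIX001-21", "BOLD", acc, "FIX001-21",
                              "ATGGCA",
                              taxon = list(organism = ranks[["species"]],
                                           taxid_hint = NA_integer_,
                                           ranks = ranks))
  structure(list(record_id = "FIX001-21", provenance = "BOLD_unique",
                 sequence = "ATGGCA", accession = acc,
                 process_id = "FIX001-21", contributing_ids = "FIX001-21",
                 ena = NULL, bold = bold), class = "coi_merged")
}

raw_ranks <- function(...) {
  r <- setNames(rep(NA_character_, 7), coiref:::COI_RANKS)
  v <- list(...)
  r[names(v)] <- unlist(v)
  r
}

test_that("BOLD-only records resolve by their lowest known rank name", {
  store <- test_store()
  res <- resolve_record_lineage(
    merged_bold(raw_ranks(species = "Vanessa atalanta")), store)
  expect_equal(unname(res$lineage$taxid[["species"]]), "42276")
  expect_equal(unname(res$lineage$name[["family"]]), "Nymphalidae")
  expect_false(res$changed)

  # species unknown, genus known: species name kept verbatim, taxid NA
  res2 <- resolve_record_lineage(
    merged_bold(raw_ranks(genus = "Vanessa", species = "Vanessa nova")),
    store)
  expect_equal(unname(res2$lineage$taxid[["genus"]]), "42275")
  expect_equal(unname(res2$lineage$name[["species"]]), "Vanessa nova")
  expect_equal(unname(res2$lineage$taxid[["species"]]), "NA")
})

test_that("names changed against the backbone are flagged and reported", {
  store <- test_store()
  rec <- merged_bold(raw_ranks(family = "Oldfamilidae",
                               species = "Vanessa atalanta"))
  res <- resolve_record_lineage(rec, store)
  expect_true(res$changed)
  expect_equal(unname(res$lineage$name[["family"]]), "Nymphalidae")

  rep <- taxonomy_update_report(list(rec), list(res))
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$old_name, "Oldfamilidae")
  expect_equal(rep$new_name, "Nymphalidae")
  expect_equal(attr(rep, "n_changed_records"), 1L)

  # unchanged record: empty report
  rec2 <- merged_bold(raw_ranks(species = "Vanessa atalanta"))
  res2 <- resolve_record_lineage(rec2, store)
  rep2 <- taxonomy_update_report(list(rec2), list(res2))
  expect_equal(nrow(rep2), 0L)
  expect_equal(attr(rep2, "n_changed_records"), 0L)

  # one record changed at two ranks: two rows, one distinct record
  rec3 <- merged_bold(raw_ranks(family = "Oldfamilidae", genus = "Oldgenus",
                                species = "Vanessa atalanta"))
  res3 <- resolve_record_lineage(rec3, store)
  rep3 <- taxonomy_update_report(list(rec3), list(res3))
  expect_equal(nrow(rep3), 2L)
  expect_equal(attr(rep3, "n_changed_records"), 1L)
})

test_that("names absent from the backbone stay verbatim with NA taxids", {
  store <- test_store()
  res <- resolve_record_lineage(
    merged_bold(raw_ranks(phylum = "Ghostophora",
                          species = "Ghostus absens")), store)
  expect_equal(unname(res$lineage$name[["phylum"]]), "Ghostophora")
  expect_equal(unname(res$lineage$name[["species"]]), "Ghostus absens")
  expect_true(all(res$lineage$taxid == "NA"))
  expect_false(res$changed)
})

test_that("accessioned records resolve through acc2taxid", {
  store <- test_store()
  rec <- merged_bold(raw_ranks(species = "ignored name"), acc = "TACC002")
  res <- resolve_record_lineage(rec, store)
  expect_equal(unname(res$lineage$name[["species"]]), "Fishus testus")
  expect_equal(unname(res$lineage$name[["phylum"]]), "Chordata")
})

test_that("homonyms are disambiguated by higher-rank ancestry", {
  dir <- write_test_taxdump()
  # add a second "Vanessa atalanta" under the chordate class
  nl <- readLines(file.path(dir, "names.dmp"))
  nd <- readLines(file.path(dir, "nodes.dmp"))
  nd <- c(nd, "99003\t|\t99001\t|\tspecies\t|\t\t|\t0\t|\t0\t|\t1\t|\t0\t|\t0\t|\t0\t|")
  nl <- c(nl, "99003\t|\tVanessa atalanta\t|\t\t|\tscientific name\t|")
  writeLines(nd, file.path(dir, "nodes.dmp"))
  writeLines(nl, file.path(dir, "names.dmp"))
  store <- read_taxdump(dir)

  res <- resolve_record_lineage(
    merged_bold(raw_ranks(class = "Actinopteri",
                          species = "Vanessa atalanta")), store)
  expect_equal(unname(res$lineage$taxid[["species"]]), "99003")
  expect_equal(unname(res$lineage$name[["class"]]), "Actinopteri")

  res2 <- resolve_record_lineage(
    merged_bold(raw_ranks(class = "Insecta",
                          species = "Vanessa atalanta")), store)
  expect_equal(unname(res2$lineage$taxid[["species"]]), "42276")

  # no disambiguating context: unresolved, with a warning
  expect_warning(res3 <- resolve_record_lineage(
    merged_bold(raw_ranks(species = "Vanessa atalanta")), store),
    "homonym")
  expect_equal(unname(res3$lineage$taxid[["species"]]), "NA")
})
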