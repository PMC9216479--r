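test_that("percentages follow the requested rounding mode", {
  expect_equal(pct_of(1, 3, 2, "half_up"), 33.33)
  expect_equal(pct_of(2, 3, 2, "half_up"), 66.67)
  expect_equal(pct_of(2, 3, 2, "truncate"), 66.66)
  expect_equal(pct_of(1, 8, 1, "half_up"), 12.5)
  expect_equal(pct_of(5, 1000, 2, "half_up"), 0.5)
  expect_true(is.na(pct_of(1, 0)))
})

mk_merged <- function(prov, id) {
  structure(list(record_id = id, provenance = prov, sequence = "ATGGCA"),
            class = "coi_merged")
}

test_that("provenance summary counts and percentages", {
  m <- list(mk_merged("BOLD_unique", "a"), mk_merged("BOLD_unique", "b"),
            mk_merged("ENA_unique", "c"), mk_merged("BOTH", "d"))
  s <- provenance_summary(m)
  expect_equal(s$count, c(2, 1, 1, 4))
  expect_equal(s$pct, c(50, 25, 25, 100))
  # percentages sum to 100 within rounding slack
  expect_lt(abs(sum(s$pct[1:3]) - 100), 0.01 * 3)

  s1 <- provenance_summary(list(mk_merged("ENA_unique", "x")))
  expect_equal(s1$pct[1:3], c(0, 100, 0))

  s0 <- provenance_summary(list())
  expect_equal(s0$count, c(0, 0, 0, 0))
  expect_true(all(is.na(s0$pct)))
})

lin <- function(phylum, class = "NA", species) {
  l <- coiref:::lineage_na()
  l$name[["phylum"]] <- phylum
  l$name[["class"]] <- class
  l$name[["species"]] <- species
  l
}

test_that("composition counts distinct names per phylum", {
  lins <- list(lin("Arthropoda", "Insecta", "Aa bb"),
               lin("Arthropoda", "Insecta", "Aa cc"),
               lin("Arthropoda", "Arachnida", "Dd ee"),
               lin("Entoprocta", species = "Ff gg"))
  comp <- composition_by_rank(lins)
  arth <- comp[comp$phylum == "Arthropoda", ]
  expect_equal(arth$seq_count, 3L)
  expect_equal(arth$class_n, 2L)
  expect_equal(arth$species_n, 3L)
  expect_equal(arth$species_pct, 75)
  # phylum with no known classes: count 0, percentage 0
  ento <- comp[comp$phylum == "Entoprocta", ]
  expect_equal(ento$class_n, 0L)
  expect_equal(ento$class_pct, 0)
  expect_equal(unname(attr(comp, "totals")[["species"]]), 4L)
  # single phylum: 100%
  comp2 <- composition_by_rank(lins[1:2])
  expect_equal(comp2$species_pct, 100)
})

test_that("disjoint phyla partition the distinct totals", {
  lins <- list(lin("A", "C1", "s1"), lin("A", "C2", "s2"),
               lin("B", "C3", "s3"))
  comp <- composition_by_rank(lins)
  expect_equal(sum(comp$species_n), unname(attr(comp, "totals")[["species"]]))
  expect_equal(sum(comp$class_n), unname(attr(comp, "totals")[["class"]]))
})

test_that("length histogram reports min, max and smallest-length mode", {
  lh <- length_histogram(c(658L, 658L, 700L))
  expect_equal(lh$mode, 658L)
  expect_equal(c(lh$min, lh$max), c(658L, 700L))
  # tie broken toward the smaller length
  expect_equal(length_histogram(c(700L, 658L, 700L, 658L))$mode, 658L)
  expect_equal(length_histogram(c(100L, 3020L))$min, 100L)
  empty <- length_histogram(integer())
  expect_equal(nrow(empty$histogram), 0L)
  expect_true(is.na(empty$mode))
})
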