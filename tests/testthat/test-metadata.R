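test_that("coordinate dialects normalize to signed decimal degrees", {
  expect_equal(unname(parse_coordinates("45.5 N 9.2 E")), c(45.5, 9.2))
  expect_equal(unname(parse_coordinates("45 30 0 S 9 15 0 W")),
               c(-45.5, -9.25))
  expect_equal(unname(parse_coordinates(c(-12.1, 44.9))), c(-12.1, 44.9))
  expect_warning(out <- parse_coordinates("91.0 N 9.2 E"), "out of range")
  expect_null(out)
  expect_null(parse_coordinates("somewhere in Italy"))
  expect_null(parse_coordinates(NA_character_))
})

test_that("coordinate formatting at 4 dp is a fixed point", {
  set.seed(17)
  for (i in 1:50) {
    lat <- runif(1, -90, 90)
    lon <- runif(1, -180, 180)
    once <- sprintf("%.4f %.4f", lat, lon)
    again <- parse_coordinates(once)
    expect_equal(sprintf("%.4f %.4f", again[["lat"]], again[["lon"]]), once)
  }
})

test_that("collection dates extract years and complete ISO dates", {
  expect_equal(parse_collection_date("12-Jul-2019"),
               list(year = 2019L, iso_date = "2019-07-12"))
  expect_equal(parse_collection_date("2019-07-12"),
               list(year = 2019L, iso_date = "2019-07-12"))
  expect_equal(parse_collection_date("2019"),
               list(year = 2019L, iso_date = "NA"))
  # two-digit years are ambiguous; free text unparseable
  expect_equal(parse_collection_date("12-Jul-19")$year, "NA")
  expect_equal(parse_collection_date("summer 2019"),
               list(year = "NA", iso_date = "NA"))
})

test_that("metadata assembly splits country, fills the nine fields", {
  store <- test_store()
  ena <- coiref:::new_record(
    "TACC001", "ENA", "TACC001", NA_character_, strrep("ACGT", 25),
    metadata = list(country = "Italy: Apulia", lat_lon = "45.50 N 9.20 E",
                    collection_date = "12-Jul-2019",
                    host = "Apis mellifera"))
  ena$mito_code <- 5L
  rec <- structure(list(record_id = "TACC001", provenance = "ENA_unique",
                        sequence = ena$sequence, accession = "TACC001",
                        process_id = NA_character_,
                        contributing_ids = "TACC001", ena = ena,
                        bold = NULL), class = "coi_merged")
  res <- resolve_record_lineage(rec, store)
  md <- build_metadata(rec, res, store)
  expect_equal(md$country, "Italy")
  expect_equal(md$region, "Apulia")
  expect_equal(md$host, "Apis mellifera")
  expect_equal(md$seq_length, "100")
  expect_equal(md$mito_gencode, "5")
  expect_equal(md$collection_year, "2019")
  expect_equal(md$collection_date, "2019-07-12")
  expect_equal(md$lat_dd, "45.5000")
  expect_equal(md$lon_dd, "9.2000")
  expect_match(md$permalink, "TACC001")
  # exactly the nine fields plus length is the fixed layout
  expect_named(md, c("seq_length", "mito_gencode", "country", "region",
                     "host", "collection_year", "collection_date",
                     "lat_dd", "lon_dd", "permalink"))
})

test_that("BOLD numeric coordinates pass through; missing fields become NA", {
  store <- test_store()
  bold <- coiref:::new_record(
    "FIX001-21", "BOLD", NA_character_, "FIX001-21", "ATGGCA",
    taxon = list(organism = "Vanessa atalanta", taxid_hint = NA_integer_,
                 ranks = setNames(c(rep(NA_character_, 6),
                                    "Vanessa atalanta"),
                                  coiref:::COI_RANKS)),
    metadata = list(lat = "-12.1", lon = "44.9", country = "Italy",
                    region = NA_character_, collection_date = NA_character_))
  rec <- structure(list(record_id = "FIX001-21",
                        provenance = "BOLD_unique", sequence = "ATGGCA",
                        accession = NA_character_,
                        process_id = "FIX001-21",
                        contributing_ids = "FIX001-21", ena = NULL,
                        bold = bold), class = "coi_merged")
  res <- resolve_record_lineage(rec, store)
  md <- build_metadata(rec, res, store)
  expect_equal(md$lat_dd, "-12.1000")
  expect_equal(md$lon_dd, "44.9000")
  expect_equal(md$country, "Italy")
  expect_equal(md$region, "NA")
  expect_equal(md$collection_year, "NA")
  expect_match(md$permalink, "FIX001-21")
})
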