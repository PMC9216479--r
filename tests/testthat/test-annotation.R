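test_that("CDS/footprint overlap arithmetic hits the 80% boundary exactly", {
  cds <- fake_cds(rbind(c(0L, 600L)))
  o <- cds_profile_overlap(cds, fake_hit(50, nt_start = 100L, nt_end = 580L))
  expect_equal(o$shared_sites, 480L)
  expect_equal(o$fraction, 0.80)
  o2 <- cds_profile_overlap(cds, fake_hit(50, nt_start = 100L, nt_end = 579L))
  expect_equal(o2$shared_sites, 479L)
  expect_lt(o2$fraction, 0.80)
})

test_that("join CDS overlaps use the union of spans", {
  cds <- fake_cds(rbind(c(0L, 30L), c(60L, 90L)))
  o <- cds_profile_overlap(cds, fake_hit(50, nt_start = 0L, nt_end = 90L))
  expect_equal(o$cds_sites, 60L)
  expect_equal(o$shared_sites, 60L)
  expect_equal(o$fraction, 1.0)
})

test_that("overlap is invariant under coordinate translation", {
  set.seed(5)
  for (i in 1:20) {
    a <- sample(0:50, 1); b <- a + sample(10:100, 1)
    h1 <- sample(0:80, 1); h2 <- h1 + sample(10:120, 1)
    d <- sample(0:1000, 1)
    o1 <- cds_profile_overlap(fake_cds(rbind(c(a, b))),
                              fake_hit(1, nt_start = h1, nt_end = h2))
    o2 <- cds_profile_overlap(fake_cds(rbind(c(a + d, b + d))),
                              fake_hit(1, nt_start = h1 + d, nt_end = h2 + d))
    expect_equal(o1$fraction, o2$fraction)
  }
})

test_that("zero-length CDS warns and yields fraction 0", {
  expect_warning(
    o <- cds_profile_overlap(fake_cds(rbind(c(10L, 10L))), fake_hit(1)),
    "zero-length")
  expect_equal(o$fraction, 0)
})

ena_rec <- function(features) {
  coiref:::new_record("ACC1", "ENA", "ACC1", NA_character_,
                      strrep("A", 700), features = features)
}

test_that("the max-overlap CDS decides and pseudogenes veto", {
  hit <- fake_hit(50, nt_start = 0L, nt_end = 600L)
  # overlaps 0.3 and 0.95 -> kept via the better CDS
  rec <- ena_rec(list(fake_cds(rbind(c(400L, 700L)), gene = "nad1"),
                      fake_cds(rbind(c(0L, 630L)), gene = "COI")))
  v <- validate_ena_record(rec, hit)
  expect_equal(v$verdict, "keep")
  expect_equal(v$best$gene, "COI")

  rec2 <- ena_rec(list(fake_cds(rbind(c(0L, 630L)), pseudo = TRUE)))
  expect_equal(validate_ena_record(rec2, hit)$verdict, "reject")

  # 80% exactly keeps (inclusive threshold)
  rec3 <- ena_rec(list(fake_cds(rbind(c(0L, 600L)), gene = "COX1")))
  v3 <- validate_ena_record(rec3, fake_hit(50, nt_start = 120L,
                                           nt_end = 600L))
  expect_equal(v3$verdict, "keep")
})

test_that("records without CDS follow the configured policy", {
  rec <- ena_rec(list())
  hit <- fake_hit(50)
  expect_equal(validate_ena_record(rec, hit)$verdict, "keep")
  cfg <- filter_config(no_cds_policy = "reject")
  expect_equal(validate_ena_record(rec, hit, cfg)$verdict, "reject")
})

test_that("synonym harvesting deduplicates, trims and sorts", {
  ov <- list(list(gene = "COI", product = NA_character_),
             list(gene = "cox1 ", product = "cytochrome oxidase subunit I"),
             list(gene = "COI", product = NA_character_))
  expect_equal(harvest_synonyms(ov),
               c("COI", "cox1", "cytochrome oxidase subunit I"))
  expect_equal(harvest_synonyms(list()), character())
})
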