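mk_ena <- function(acc) coiref:::new_record(acc, "ENA", acc, NA_character_,
                                            "ATGGCA")
mk_bold <- function(pid, acc = NA_character_) {
  coiref:::new_record(if (!is.na(acc)) acc else pid, "BOLD", acc, pid,
                      "ATGGCATT")
}

test_that("accession joins yield BOTH records with ENA sequence precedence", {
  m <- merge_sources(list(mk_ena("ACC1"), mk_ena("ACC9")),
                     list(mk_bold("FIX001-21", "ACC1"),
                          mk_bold("FIX002-21")))
  prov <- vapply(m$records, function(r) r$provenance, character(1))
  ids <- vapply(m$records, function(r) r$record_id, character(1))
  expect_setequal(paste(ids, prov),
                  c("ACC1 BOTH", "ACC9 ENA_unique",
                    "FIX002-21 BOLD_unique"))
  both <- m$records[[which(ids == "ACC1")]]
  expect_equal(both$sequence, "ATGGCA")          # ENA side wins
  expect_equal(both$process_id, "FIX001-21")
  expect_equal(m$dropped, 0L)
})

test_that("merge counts satisfy the partition identity", {
  set.seed(21)
  for (i in 1:5) {
    n_e <- sample(3:10, 1); n_b <- sample(3:10, 1)
    n_shared <- sample(0:min(n_e, n_b), 1)
    ena <- lapply(seq_len(n_e), function(j) mk_ena(sprintf("ACC%03d", j)))
    bold <- lapply(seq_len(n_b), function(j) {
      mk_bold(sprintf("FIX%03d-21", j),
              if (j <= n_shared) sprintf("ACC%03d", j) else NA_character_)
    })
    m <- merge_sources(ena, bold)
    prov <- table(factor(vapply(m$records, function(r) r$provenance,
                                character(1)),
                         c("BOLD_unique", "ENA_unique", "BOTH")))
    expect_equal(length(m$records), sum(prov))
    expect_equal(n_e, unname(prov[["ENA_unique"]] + prov[["BOTH"]]))
    expect_equal(n_b, unname(prov[["BOLD_unique"]] + prov[["BOTH"]]))
    # ids unique in the merged set
    ids <- vapply(m$records, function(r) r$record_id, character(1))
    expect_false(anyDuplicated(ids) > 0)
  }
})

test_that("merging is idempotent on its own output", {
  m <- merge_sources(list(mk_ena("ACC1")), list(mk_bold("FIX001-21", "ACC1"),
                                                mk_bold("FIX002-21")))
  # feed the merged records back as one source against nothing
  again <- merge_sources(lapply(m$records, function(r) {
    coiref:::new_record(r$record_id, "ENA", r$record_id, NA_character_,
                        r$sequence)
  }), list())
  expect_equal(length(again$records), length(m$records))
})

test_that("intra-source duplicates collapse with a warning", {
  expect_warning(m <- merge_sources(list(mk_ena("ACC1"), mk_ena("ACC1")),
                                    list()),
                 "duplicate")
  expect_length(m$records, 1L)
})

test_that("BOLD records with no usable id are dropped and counted", {
  b <- mk_bold("FIX001-21")
  b$process_id <- NA_character_
  b$record_id <- NA_character_
  m <- merge_sources(list(), list(b))
  expect_length(m$records, 0L)
  expect_equal(m$dropped, 1L)
})
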