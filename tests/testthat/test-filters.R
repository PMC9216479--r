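rec_of_len <- function(L, source = "ENA") {
  coiref:::new_record("R1", source, "R1", NA_character_, strrep("A", L))
}

test_that("length window bounds are inclusive", {
  cfg <- filter_config()
  expect_false(length_gate(rec_of_len(99), cfg))
  expect_true(length_gate(rec_of_len(100), cfg))
  expect_true(length_gate(rec_of_len(658), cfg))
  expect_true(length_gate(rec_of_len(60000), cfg))
  expect_false(length_gate(rec_of_len(60001), cfg))
})

test_that("length gate can be restricted to ENA records", {
  cfg <- filter_config(apply_length_to = "ENA_only")
  expect_true(length_gate(rec_of_len(99, source = "BOLD"), cfg))
  expect_false(length_gate(rec_of_len(99, source = "ENA"), cfg))
})

test_that("terminal-N trimming removes maximal runs and is idempotent", {
  tr <- trim_terminal_n("NNNATGCNNATGCNN")
  expect_equal(tr$sequence, "ATGCNNATGC")
  expect_equal(c(tr$n_leading, tr$n_trailing), c(3L, 2L))
  expect_equal(trim_terminal_n("ATGC")$sequence, "ATGC")
  tr2 <- trim_terminal_n("NNNN")
  expect_equal(tr2$sequence, "")
  expect_equal(c(tr2$n_leading, tr2$n_trailing), c(4L, 0L))
  # idempotence on random sequences
  set.seed(3)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 30, replace = TRUE,
                      prob = c(1, 1, 1, 1, 2)), collapse = "")
    once <- trim_terminal_n(s)$sequence
    expect_identical(trim_terminal_n(once)$sequence, once)
  }
})

test_that("internal-N cap passes five and fails six", {
  cfg <- filter_config()
  expect_true(internal_n_gate(paste0("AC", strrep("NA", 5), "GT"), cfg))
  expect_false(internal_n_gate(paste0("AC", strrep("NA", 6), "GT"), cfg))
  expect_true(internal_n_gate("ACGT", cfg))
  # other ambiguity codes are not counted
  expect_true(internal_n_gate(paste0("AC", strrep("RY", 6), "GT"), cfg))
})

test_that("stop-codon gate honours the envelope scope", {
  hit <- fake_hit(50, aa_start = 0L, aa_end = 6L,
                  peptide = "MAW*LH")
  expect_false(stop_codon_gate(hit, filter_config()))
  # stop outside the envelope passes under envelope scope ...
  hit2 <- fake_hit(50, aa_start = 0L, aa_end = 3L, peptide = "MAW*LH")
  expect_true(stop_codon_gate(hit2, filter_config()))
  # ... but fails under full-frame scope
  expect_false(stop_codon_gate(hit2,
                               filter_config(stop_check_scope = "full_frame")))
  hit3 <- fake_hit(50, aa_start = 0L, aa_end = 6L, peptide = "MAWQLH")
  expect_true(stop_codon_gate(hit3, filter_config()))
})
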