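test_that("local Viterbi matches exhaustive enumeration on small cases", {
  set.seed(11)
  for (i in 1:60) {
    M <- sample(1:3, 1)
    p <- random_toy_profile(M)
    pep <- paste(sample(c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X"),
                        sample(1:4, 1), replace = TRUE), collapse = "")
    got <- viterbi_local(p, pep)$score_bits
    want <- bf_viterbi_score(p$match_bits, p$trans_bits, pep_to_idx(pep))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("empty peptides score -Inf; unknown residues emit 0 bits", {
  p <- test_profile("MAW")
  expect_equal(viterbi_local(p, "")$score_bits, -Inf)
  # a single X scores exactly the entry+exit path: 0 bits
  expect_equal(viterbi_local(p, "X")$score_bits, 0)
})

test_that("appending residues never decreases a local alignment score", {
  set.seed(13)
  p <- random_toy_profile(3)
  for (i in 1:25) {
    pep <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                        sample(2:6, 1), replace = TRUE), collapse = "")
    s1 <- viterbi_local(p, pep)$score_bits
    s2 <- viterbi_local(p, paste0(pep, "W"))$score_bits
    s3 <- viterbi_local(p, paste0("W", pep))$score_bits
    expect_gte(s2, s1)
    expect_gte(s3, s1)
  }
})

test_that("the envelope covers the matched residues", {
  p <- test_profile("MAWHK")
  v <- viterbi_local(p, "VVMAWHKVV")
  expect_equal(v$aa_start, 2L)
  expect_equal(v$aa_end, 7L)
})

test_that("frame envelopes map to forward nucleotide coordinates", {
  p <- test_profile("MA")
  # plant M-A at aa [2,4) of frame +2 (offset 1) on a 20 nt sequence
  s <- paste0("C", "CCTCCT", "ATGGCA", "CCTCCTC")
  expect_equal(nchar(s), 20L)
  hit <- best_frame_hit(p, six_frame_translate(s, genetic_code(5)), 20L)
  expect_equal(hit$frame, "+2")
  expect_equal(c(hit$nt_start, hit$nt_end), c(7L, 13L))
  expect_equal(hit$nt_end - hit$nt_start, 3L * (hit$aa_end - hit$aa_start))

  # plant at aa [0,2) of frame -1: forward sequence ends with revcomp(ATGGCA)
  s2 <- paste0(strrep("CCT", 4), "CT", "TGCCAT")
  expect_equal(nchar(s2), 20L)
  hit2 <- best_frame_hit(p, six_frame_translate(s2, genetic_code(5)), 20L)
  expect_equal(hit2$frame, "-1")
  expect_equal(c(hit2$nt_start, hit2$nt_end), c(14L, 20L))
})

test_that("equal frame scores prefer the earlier frame", {
  p <- test_profile("MH")
  s <- "ATGCAT"  # reverse-complement palindrome: frames +1 and -1 identical
  fr <- six_frame_translate(s, genetic_code(5))
  expect_identical(fr[[1]]$peptide, fr[[4]]$peptide)
  hit <- best_frame_hit(p, fr, nchar(s))
  expect_equal(hit$frame, "+1")
})

test_that("the trusted-cutoff gate is inclusive and monotone", {
  p <- test_profile("MA", tc = 34)
  expect_true(passes_tc(fake_hit(34.0), p))
  expect_false(passes_tc(fake_hit(33.99), p))
  # raising the cutoff never accepts a previously rejected hit
  for (s in c(20, 33.99, 34, 50)) {
    for (tc1 in c(20, 34)) {
      for (tc2 in c(34, 60)) {
        if (tc2 >= tc1 && passes_tc(fake_hit(s), p, tc_override = tc2)) {
          expect_true(passes_tc(fake_hit(s), p, tc_override = tc1))
        }
      }
    }
  }
})

test_that("domtblout parsing keeps the best domain per query", {
  f <- tempfile()
  writeLines(c(
    "# comment",
    paste("SEQ1 - 219 COI_toy - 219 1e-50 180.0 0.1 1 2 1e-20 1e-21 40.1",
          "0.0 1 199 12 210 12 210 0.9 -"),
    paste("SEQ1 - 219 COI_toy - 219 1e-50 180.0 0.1 2 2 1e-10 1e-11 20.5",
          "0.0 1 99 300 398 300 398 0.9 -"),
    paste("SEQ2 - 219 COI_toy - 219 1e-5 30.0 0.1 1 1 1e-5 1e-6 30.0",
          "0.0 1 99 5 103 5 103 0.9 -"),
    "not a valid line"), f)
  expect_warning(read_domtbl(f), "malformed")
  hits <- suppressWarnings(read_domtbl(f))
  expect_named(hits, c("SEQ1", "SEQ2"))
  expect_equal(hits[["SEQ1"]]$score_bits, 40.1)
  expect_equal(c(hits[["SEQ1"]]$aa_start, hits[["SEQ1"]]$aa_end),
               c(11L, 210L))

  f2 <- tempfile(); writeLines("# only comments", f2)
  expect_length(read_domtbl(f2), 0L)
})
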