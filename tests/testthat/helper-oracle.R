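# Independent oracle for the plan7-lite local Viterbi: exhaustive
# enumeration of every local alignment path (entry at any match state and
# residue, exit at any match state), implemented recursively and entirely
# apart from the DP code it checks. Feasible for tiny models/peptides.

bf_viterbi_score <- function(match_bits, trans_bits, pep_idx) {
  M <- nrow(match_bits)
  L <- length(pep_idx)
  if (L == 0L || M == 0L) return(-Inf)
  best <- -Inf
  emit <- function(k, j) {
    r <- pep_idx[j]
    if (r < 0L) 0 else unname(match_bits[k, r + 1L])
  }
  rec <- function(state, k, j, acc) {
    if (state == "M") {
      if (acc > best) best <<- unname(acc)
      if (j < L && k < M) rec("M", k + 1L, j + 1L,
                              acc + trans_bits[k, 1] + emit(k + 1L, j + 1L))
      if (j < L) rec("I", k, j + 1L, acc + trans_bits[k, 2])
      if (k < M) rec("D", k + 1L, j, acc + trans_bits[k, 3])
    } else if (state == "I") {
      if (j < L) rec("I", k, j + 1L, acc + trans_bits[k, 5])
      if (j < L && k < M) rec("M", k + 1L, j + 1L,
                              acc + trans_bits[k, 4] + emit(k + 1L, j + 1L))
    } else {
      if (k < M) rec("D", k + 1L, j, acc + trans_bits[k, 7])
      if (j < L && k < M) rec("M", k + 1L, j + 1L,
                              acc + trans_bits[k, 6] + emit(k + 1L, j + 1L))
    }
  }
  for (k in seq_len(M)) {
    for (j in seq_len(L)) {
      rec("M", k, j, emit(k, j))
    }
  }
  best
}

# a random small profile object usable by viterbi_local()
random_toy_profile <- function(M) {
  mb <- matrix(runif(M * 20, -3, 4), M, 20,
               dimnames = list(NULL, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  tb <- matrix(log2(runif(M * 7, 0.05, 0.95)), M, 7,
               dimnames = list(NULL, c("mm", "mi", "md", "im", "ii", "dm",
                                       "dd")))
  structure(list(name = "rand", M = M, match_bits = mb,
                 insert_bits = mb * 0, trans_bits = tb, tc = NA_real_,
                 ga = NA_real_, nc = NA_real_),
            class = "coi_profile")
}

pep_to_idx <- function(pep) {
  i <- match(strsplit(pep, "")[[1]], strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  i[is.na(i)] <- 0L
  i - 1L
}
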