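#' Read a HMMER3 ASCII profile
#'
#' Parses the `HMMER3/f` text format for amino-acid profiles. Match and
#' insert emissions are converted from the file's negative-log
#' probabilities to log-odds bits against the file's null model (taken,
#' as in HMMER, from the node-0 insert emission line); transition scores
#' become `log2` of their probabilities. `GA`/`TC`/`NC` Pfam cutoff lines
#' are captured when present. Zero-probability transitions (`*`) map to a
#' large finite penalty so every stored score stays finite.
#'
#' @param path path to a profile file; only the first model is read.
#' @return object of class `coi_profile`: `name`, `M`, `match_bits`
#'   (M x 20, columns in HMMER amino order `ACDEFGHIKLMNPQRSTVWY`),
#'   `insert_bits`, `trans_bits` (M x 7: m->m, m->i, m->d, i->m, i->i,
#'   d->m, d->d), `bg` (null frequencies), and cutoffs `tc`, `ga`, `nc`
#'   (`NA` when absent).
#' @export
read_hmm_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hmm_at <- grep("^HMM\\s", lines)[1]
  if (is.na(hmm_at)) stop("not a HMMER3 ASCII profile: no HMM line")
  header <- lines[seq_len(hmm_at - 1L)]

  field <- function(tag) {
    l <- grep(paste0("^", tag, "\\s"), header, value = TRUE)
    if (!length(l)) return(NA_character_)
    trimws(sub(paste0("^", tag, "\\s+"), "", l[1]))
  }
  alph <- field("ALPH")
  if (is.na(alph) || tolower(alph) != "amino") {
    stop("profile alphabet is '", alph, "'; an amino-acid profile is required")
  }
  name <- field("NAME") %||% "profile"
  M <- as.integer(field("LENG"))
  cutoff <- function(tag) {
    v <- field(tag)
    if (is.na(v)) return(NA_real_)
    as.numeric(sub("^([0-9.+-eE]+).*", "\\1", v))
  }

  body <- lines[(hmm_at + 2L):length(lines)]  # skip HMM + transition header
  body <- body[!grepl("^//", body)]
  toks <- lapply(trimws(body), function(l) strsplit(l, "\\s+")[[1]])
  toks <- toks[vapply(toks, length, 1L) > 0L]

  num <- function(x) {
    v <- suppressWarnings(as.numeric(x))
    v[x == "*"] <- Inf  # -ln(0)
    v
  }

  i <- 1L
  if (identical(toks[[i]][1], "COMPO")) i <- i + 1L
  bg_nl <- num(toks[[i]][1:20]); i <- i + 1L   # node-0 insert emissions = null
  bg <- exp(-bg_nl)
  i <- i + 1L                                  # node-0 transition line

  match_bits <- matrix(NA_real_, M, 20, dimnames = list(NULL, AA20))
  insert_bits <- matrix(NA_real_, M, 20, dimnames = list(NULL, AA20))
  trans_bits <- matrix(NA_real_, M, 7,
                       dimnames = list(NULL, c("mm", "mi", "md", "im", "ii",
                                               "dm", "dd")))
  to_bits <- function(neglog, null_neglog = 0) {
    b <- (-neglog + null_neglog) / log(2)
    b[!is.finite(b)] <- -1e6
    b
  }
  for (k in seq_len(M)) {
    mt <- toks[[i]]; i <- i + 1L
    if (as.integer(mt[1]) != k) stop("malformed profile: node ", k)
    match_bits[k, ] <- to_bits(num(mt[2:21]), -log(bg))
    insert_bits[k, ] <- to_bits(num(toks[[i]][1:20]), -log(bg)); i <- i + 1L
    trans_bits[k, ] <- to_bits(num(toks[[i]][1:7])); i <- i + 1L
  }

  structure(list(name = name, M = M, match_bits = match_bits,
                 insert_bits = insert_bits, trans_bits = trans_bits,
                 bg = setNames(bg, AA20),
                 tc = cutoff("TC"), ga = cutoff("GA"), nc = cutoff("NC")),
            class = "coi_profile")
}

#' @export
print.coi_profile <- function(x, ...) {
  cat(sprintf("<coi_profile %s M=%d TC=%s>\n", x$name, x$M,
              ifelse(is.na(x$tc), "unset", format(x$tc))))
  invisible(x)
}
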