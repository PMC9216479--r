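#' Read NCBI taxdump files into a taxonomy store
#'
#' Parses the `.dmp` dialect (fields separated by `"\t|\t"`, rows ending
#' `"\t|"`) of `nodes.dmp`, `names.dmp` and optionally `gencode.dmp`.
#' Only names of class `scientific name` enter the name-to-taxid index
#' (case-insensitive keys); unknown rank labels are preserved verbatim.
#' The mitochondrial genetic-code id of each node is stored as given
#' (0 = unset) and resolved by nearest-ancestor lookup in
#' [mito_code_for()]. Cyclic parent links (other than the root's
#' self-link) are a fatal error.
#'
#' @param dir directory containing the dump files, or `NULL` when paths
#'   are given explicitly.
#' @param nodes,names_,gencode explicit file paths (override `dir`).
#' @return object of class `coi_taxstore` with fields `parent`, `rank`,
#'   `name` (named by taxid), `name2tax` (lower-cased name -> integer
#'   taxids), `mgc`, `gencodes` (parsed translation tables) and an
#'   initially empty `acc2taxid`.
#' @export
read_taxdump <- function(dir = NULL, nodes = NULL, names_ = NULL,
                         gencode = NULL) {
  p <- function(x, f) x %||% file.path(dir, f)
  nodes <- p(nodes, "nodes.dmp")
  names_ <- p(names_, "names.dmp")
  gencode <- gencode %||%
    (if (!is.null(dir) && file.exists(file.path(dir, "gencode.dmp")))
       file.path(dir, "gencode.dmp") else NULL)

  nd <- read_dmp(nodes)
  taxid <- nd[[1]]
  parent <- setNames(as.integer(nd[[2]]), taxid)
  rank <- setNames(nd[[3]], taxid)
  mgc <- if (length(nd) >= 9) setNames(as.integer(nd[[9]]), taxid) else
    setNames(rep(0L, length(taxid)), taxid)

  # root + cycle check
  root <- taxid[nd[[1]] == nd[[2]]]
  if (length(root) != 1L) {
    stop("taxonomy must contain exactly one root (parent == self), found ",
         length(root))
  }
  for (t in taxid) {
    seen <- character()
    cur <- t
    while (cur != as.character(root)) {
      if (cur %in% seen) stop("cyclic parent links at taxid ", t)
      seen <- c(seen, cur)
      nxt <- as.character(parent[[cur]])
      if (!(nxt %in% names(parent))) stop("dangling parent for taxid ", cur)
      cur <- nxt
    }
  }

  nm <- read_dmp(names_)
  sci <- nm[[4]] == "scientific name"
  name <- setNames(nm[[2]][sci], nm[[1]][sci])
  name2tax <- split(as.integer(nm[[1]][sci]), tolower(nm[[2]][sci]))

  gencodes <- list()
  if (!is.null(gencode)) {
    gc <- read_dmp(gencode)
    for (i in seq_along(gc[[1]])) {
      id <- as.integer(gc[[1]][i])
      if (id > 0L && nchar(gsub("\\s", "", gc[[4]][i])) == 64L) {
        gencodes[[as.character(id)]] <- genetic_code_from_cde(id, gc[[4]][i])
      }
    }
  }

  structure(list(parent = parent, rank = rank, name = name,
                 name2tax = name2tax, mgc = mgc, gencodes = gencodes,
                 root = as.integer(root),
                 acc2taxid = setNames(integer(), character())),
            class = "coi_taxstore")
}

read_dmp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\t\\|$", "", lines)
  parts <- strsplit(lines, "\t\\|\t")
  n <- max(vapply(parts, length, 1L))
  lapply(seq_len(n), function(i) {
    vapply(parts, function(p) if (length(p) >= i) p[i] else "", character(1))
  })
}

#' Read an accession-to-taxid mapping
#'
#' Four-column TSV with a header (`accession`, `accession.version`,
#' `taxid`, `gi`); accessions are keyed versionless.
#'
#' @param path path to the mapping file.
#' @return named integer vector, accession -> taxid.
#' @export
read_acc2taxid <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(as.integer(df[[3]]), strip_version(df[[1]]))
}

#' @export
print.coi_taxstore <- function(x, ...) {
  cat(sprintf("<coi_taxstore %d taxa, %d names, %d gencodes, %d accessions>\n",
              length(x$parent), length(x$name), length(x$gencodes),
              length(x$acc2taxid)))
  invisible(x)
}
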