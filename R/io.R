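# Sequence and tree I/O.  Sequence sets are plain named character vectors
# (names = identifiers, values = residue strings over the 20 amino-acid
# letters plus '-'); trees are ape "phylo" objects.

.valid_residues <- function() c(.aa, "-")

# Validate a sequence set; aligned = TRUE additionally requires equal widths.
assert_seqs <- function(seqs, aligned = FALSE) {
  if (!is.character(seqs)) stop("sequence set must be a character vector")
  ids <- names(seqs)
  if (length(seqs) > 0 && (is.null(ids) || any(ids == "")))
    stop("all sequences must carry non-empty identifiers")
  if (anyDuplicated(ids))
    stop("duplicate sequence identifier: ", ids[duplicated(ids)][1])
  bad <- grepl(paste0("[^", paste(.valid_residues(), collapse = ""), "]"), seqs)
  if (any(bad))
    stop("sequence '", ids[bad][1],
         "' contains residues outside the 20-letter alphabet plus '-'")
  if (aligned && length(seqs) > 0 && length(unique(nchar(seqs))) != 1)
    stop("aligned sequence set must have equal-length sequences")
  invisible(seqs)
}

#' Read amino-acid sequences from a FASTA file
#'
#' Strict single-dialect reader: record order preserved, residues
#' upper-cased, whitespace inside sequence lines stripped.  Identifiers are
#' the header up to the first whitespace and must be unique.  Residues
#' outside the 20 amino-acid letters plus the gap character `-` (including
#' `X` and `.`) are rejected.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) return(structure(character(0), names = character(0)))
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1])
    stop("FASTA parse error at line ", lineno[1], ": expected '>' header")
  rec <- cumsum(is_hdr)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[is_hdr]))
  if (any(ids == "")) {
    bad <- lineno[is_hdr][ids == ""][1]
    stop("FASTA parse error at line ", bad, ": empty identifier")
  }
  seqs <- vapply(seq_along(ids), function(i) {
    body <- lines[rec == i & !is_hdr]
    toupper(gsub("\\s", "", paste(body, collapse = "")))
  }, character(1))
  empty <- nchar(seqs) == 0
  if (any(empty)) {
    bad <- lineno[is_hdr][empty][1]
    stop("FASTA parse error at line ", bad, ": record '",
         ids[empty][1], "' has an empty sequence")
  }
  names(seqs) <- ids
  assert_seqs(seqs)
}

#' Write sequences as FASTA (60-column wrapping)
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @export
write_fasta <- function(seqs, path) {
  assert_seqs(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, max(nchar(s), 1), by = 60)
    writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
  }
  invisible(path)
}

#' Read a Newick tree string
#'
#' Unrooted trees are stored with their trifurcating (or multifurcating)
#' root as written; absent branch lengths default to 0.
#'
#' @param text Newick string (must end in `;`).
#' @return an ape `phylo` object.
#' @export
read_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("Newick parse error in: ", text)
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  tr$edge.length[is.na(tr$edge.length)] <- 0
  tr
}

#' Write a tree as a Newick string
#' @param tree an ape `phylo` object.
#' @return Newick string with branch lengths.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

#' Remove gaps from aligned sequences
#' @param seqs named character vector (aligned or not).
#' @return the same sequences with every `-` removed, order preserved.
#' @export
strip_gaps <- function(seqs) {
  assert_seqs(seqs)
  out <- gsub("-", "", seqs, fixed = TRUE)
  names(out) <- names(seqs)
  out
}

# Character-matrix view of an aligned sequence set (rows = sequences).
seqs_to_matrix <- function(seqs) {
  assert_seqs(seqs, aligned = TRUE)
  if (length(seqs) == 0) return(matrix(character(0), 0, 0))
  m <- do.call(rbind, strsplit(seqs, NULL))
  rownames(m) <- names(seqs)
  m
}

matrix_to_seqs <- function(m) {
  out <- apply(m, 1, paste, collapse = "")
  names(out) <- rownames(m)
  out
}

# phangorn phyDat view ('-' is treated as missing data by phyDat's AA
# contrast, which is the gap handling the likelihood engine relies on).
seqs_to_phydat <- function(seqs) {
  phangorn::phyDat(seqs_to_matrix(seqs), type = "AA")
}
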