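# Progressive multiple sequence alignment (a MUSCLE-class stand-in used by
# the similarity-conditioning and permutation experiments) and the pairwise
# identity statistics those experiments score.

# BLOSUM62 (half-bit scores), rows/columns in A,R,N,...,V order.
.blosum62 <- local({
  v <- c(
     4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,
    -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,
    -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,
    -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,
     0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,
    -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,
    -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,
     0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,
    -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,
    -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,
    -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,
    -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2,
    -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,
    -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,
    -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,
     1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2,
     0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,
    -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,
    -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,
     0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4)
  matrix(v, 20, 20, byrow = TRUE,
         dimnames = list(.aa, .aa))
})

#' BLOSUM62 substitution scores used by the aligner
#' @return 20x20 integer score matrix in A,R,N,...,V order.
#' @export
blosum62 <- function() .blosum62

# integer encoding of sequences: 0 = gap, 1..20 = state
.encode_seq <- function(s) {
  i <- match(strsplit(s, NULL)[[1]], c("-", .aa)) - 1L
  if (anyNA(i)) stop("unknown residue in sequence")
  i
}

.decode_row <- function(v) paste(c("-", .aa)[v + 1L], collapse = "")

#' Pairwise identity of two aligned sequences
#'
#' Fraction of matching residues among the columns where neither sequence
#' has a gap; 0 when no such column exists.
#'
#' @param s1,s2 equal-length gapped residue strings.
#' @return identity in `[0, 1]`.
#' @export
pairwise_identity <- function(s1, s2) {
  if (nchar(s1) != nchar(s2)) stop("sequences must have equal aligned length")
  a <- strsplit(s1, NULL)[[1]]
  b <- strsplit(s2, NULL)[[1]]
  ok <- a != "-" & b != "-"
  if (!any(ok)) return(0)
  mean(a[ok] == b[ok])
}

#' Identity summary of an aligned sequence set
#'
#' Computes the full pairwise identity matrix, the unweighted mean over
#' pairs, and -- when a two-or-more-group partition is supplied -- the
#' within-group minus between-group average identity, the second summary
#' statistic of the permutation test.
#'
#' @param seqs aligned named character vector.
#' @param partition optional named list of identifier vectors.
#' @return list with `pairwise`, `average` and (with a partition)
#'   `within_minus_between`.
#' @export
identity_summary <- function(seqs, partition = NULL) {
  assert_seqs(seqs, aligned = TRUE)
  n <- length(seqs)
  if (n < 2) stop("need at least 2 sequences")
  m <- matrix(1, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      m[i, j] <- m[j, i] <- pairwise_identity(seqs[[i]], seqs[[j]])
  out <- list(pairwise = m, average = mean(m[upper.tri(m)]))
  if (!is.null(partition)) {
    out$within_minus_between <-
      average_identity(seqs, partition, "within", .pairwise = m) -
      average_identity(seqs, partition, "between", .pairwise = m)
  }
  out
}

#' Average pairwise identity over selected pairs
#'
#' @param seqs aligned named character vector.
#' @param partition named list of identifier vectors (required for the
#'   `"within"` and `"between"` modes).
#' @param pairs which pairs to average over.
#' @param .pairwise optional precomputed identity matrix.
#' @return mean identity over the selected pairs.
#' @export
average_identity <- function(seqs, partition = NULL,
                             pairs = c("all", "within", "between"),
                             .pairwise = NULL) {
  pairs <- match.arg(pairs)
  m <- if (is.null(.pairwise)) identity_summary(seqs)$pairwise else .pairwise
  ids <- rownames(m)
  if (pairs == "all") return(mean(m[upper.tri(m)]))
  if (is.null(partition)) stop("a partition is required for pairs = ", pairs)
  assert_partition(partition, ids)
  grp <- group_of(partition, ids)
  same <- outer(grp, grp, "==")
  sel <- upper.tri(m) & (if (pairs == "within") same else !same)
  if (pairs == "within" && any(vapply(partition, length, 1L) < 2))
    stop("each group needs >= 2 sequences for within-group identity")
  mean(m[sel])
}

# 3-mer shared-fraction distance for the initial guide tree:
# d = 1 - sum_k min(count_a, count_b) / (shorter sequence's kmer count).
# (A count *cosine* is useless here: it tends to 1 between unrelated
# sequences of the same composition as length grows.)
.kmer_distance <- function(seqs, k = 3L) {
  profs <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(table(s))
    table(substring(s, 1:(n - k + 1), k:n))
  })
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- profs[[i]]; b <- profs[[j]]
    keys <- intersect(names(a), names(b))
    shared <- sum(pmin(as.numeric(a[keys]), as.numeric(b[keys])))
    f <- shared / min(sum(a), sum(b))
    d[i, j] <- d[j, i] <- 1 - f
  }
  d
}

.merge_profiles <- function(a, b, gap_open, gap_ext) {
  al <- .align_profiles_cpp(a, b, .blosum62, gap_open, gap_ext)
  la <- length(al$a_path)
  out <- matrix(0L, nrow(a) + nrow(b), la)
  rownames(out) <- c(rownames(a), rownames(b))
  ga <- al$a_path > 0L
  gb <- al$b_path > 0L
  out[seq_len(nrow(a)), ga] <- a[, al$a_path[ga], drop = FALSE]
  out[nrow(a) + seq_len(nrow(b)), gb] <- b[, al$b_path[gb], drop = FALSE]
  attr(out, "score") <- al$score
  out
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps, BLOSUM62)
#'
#' @param s1,s2 ungapped residue strings (non-empty).
#' @param gap_open,gap_ext gap penalties (positive costs; a gap of length g
#'   costs `gap_open + g * gap_ext`).
#' @return list with the two aligned strings (`alignment`) and the optimal
#'   `score`.
#' @export
pairwise_align <- function(s1, s2, gap_open = 10, gap_ext = 1) {
  if (nchar(s1) == 0 || nchar(s2) == 0) stop("empty sequence")
  a <- matrix(.encode_seq(s1), 1)
  b <- matrix(.encode_seq(s2), 1)
  if (any(a == 0L) || any(b == 0L)) stop("input sequences must be ungapped")
  m <- .merge_profiles(a, b, gap_open, gap_ext)
  list(alignment = c(.decode_row(m[1, ]), .decode_row(m[2, ])),
       score = attr(m, "score"))
}

#' Progressive multiple sequence alignment
#'
#' Profile-profile progressive alignment along a neighbour-joining guide
#' tree, scoring columns by the mean BLOSUM62 score over cross pairs with
#' affine gap penalties.  The first pass builds the guide tree from 3-mer
#' shared-fraction distances; with `refine = TRUE` (default) a second pass
#' rebuilds the guide tree from the pairwise identities of the first-pass
#' alignment and realigns, which protects the guide tree against the
#' alignment-free distances' noise on weakly similar sequences.
#' Stripping the gaps from the result recovers the inputs exactly.
#'
#' @param seqs ungapped named character vector (>= 2 sequences).
#' @param refine rebuild the guide tree from the first-pass alignment?
#' @inheritParams pairwise_align
#' @return aligned named character vector in the input order.
#' @export
progressive_align <- function(seqs, gap_open = 10, gap_ext = 1,
                              refine = TRUE) {
  assert_seqs(seqs)
  if (length(seqs) < 2) stop("need at least 2 sequences")
  if (any(grepl("-", seqs, fixed = TRUE))) stop("input sequences must be ungapped")
  if (any(nchar(seqs) == 0)) stop("empty sequence")
  profs <- lapply(seq_along(seqs), function(i) {
    m <- matrix(.encode_seq(seqs[[i]]), 1)
    rownames(m) <- names(seqs)[i]
    m
  })
  n <- length(seqs)
  if (n == 2) {
    m <- .merge_profiles(profs[[1]], profs[[2]], gap_open, gap_ext)
  } else {
    guide <- .rooted_guide(.kmer_distance(seqs))
    m <- .align_along_tree(guide, profs, names(seqs), gap_open, gap_ext)
    if (refine) {
      aln1 <- vapply(seq_len(nrow(m)), function(i) .decode_row(m[i, ]),
                     character(1))
      names(aln1) <- rownames(m)
      guide2 <- .rooted_guide(1 - identity_summary(aln1)$pairwise)
      m <- .align_along_tree(guide2, profs, names(seqs), gap_open, gap_ext)
    }
  }
  out <- vapply(seq_len(nrow(m)), function(i) .decode_row(m[i, ]), character(1))
  names(out) <- rownames(m)
  out[names(seqs)]
}

# Midpoint-rooted NJ guide tree: rooting on the longest path keeps each
# clade's merges contiguous (an arbitrary NJ root can fall inside a tight
# cluster and split it across the final profile merge).
.rooted_guide <- function(d) {
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length <- pmax(tr$edge.length, 0)
  out <- try(phangorn::midpoint(tr), silent = TRUE)
  if (inherits(out, "try-error") || !inherits(out, "phylo")) tr else out
}

# Postorder profile merge along a rooted guide tree.
.align_along_tree <- function(tree, profs, ids, gap_open, gap_ext) {
  ntip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  build <- function(node) {
    if (node <= ntip) return(profs[[match(tree$tip.label[node], ids)]])
    kids <- children[[as.character(node)]]
    acc <- build(kids[1])
    for (k in kids[-1])
      acc <- .merge_profiles(acc, build(k), gap_open, gap_ext)
    acc
  }
  build(ntip + 1L)
}
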