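# Frequentist column-permutation test of common ancestry: destroy the
# cross-group column homology of one group, realign, recompute a summary
# statistic, and compare the observed value against that null sample.

#' Shuffle the column order of one group
#'
#' Extracts the group's rows from the alignment, permutes their columns by
#' one shared random permutation (preserving the within-group column
#' covariance while destroying any cross-group homology), drops columns
#' that are all-gap within the group, strips gaps, and returns the pooled
#' unaligned sequence set ready for realignment.  Non-group rows are
#' gap-stripped unchanged.
#'
#' @param seqs aligned named character vector.
#' @param group identifiers of the group to shuffle (a proper non-empty
#'   subset).
#' @param seed optional integer seed (same seed, same permutation).
#' @return unaligned named character vector in the input order.
#' @export
shuffle_group_columns <- function(seqs, group, seed = NULL) {
  assert_seqs(seqs, aligned = TRUE)
  if (length(group) == 0 || !all(group %in% names(seqs)))
    stop("group must be a non-empty subset of the sequence identifiers")
  if (setequal(group, names(seqs)))
    stop("group must be a proper subset (shuffling all rows is meaningless)")
  m <- seqs_to_matrix(seqs)
  sub <- m[group, , drop = FALSE]
  keep <- colSums(sub != "-") > 0
  sub <- sub[, keep, drop = FALSE]
  perm <- with_seed(seed, sample.int(ncol(sub)))
  sub <- sub[, perm, drop = FALSE]
  out <- seqs
  out[group] <- gsub("-", "", apply(sub, 1, paste, collapse = ""), fixed = TRUE)
  out[setdiff(names(seqs), group)] <-
    strip_gaps(seqs[setdiff(names(seqs), group)])
  out[names(seqs)]
}

# Summary statistics on an aligned pooled set.
.perm_statistic <- function(aligned, partition, statistic, tree_search) {
  if (statistic == "tree_length") {
    d <- seqs_to_phydat(aligned)
    fit <- if (tree_search == "nni") ml_tree(d, "LG")
           else .fit_on_tree(d, nj_tree(ml_distances(d)), "LG")
    tree_length(fit$tree)
  } else {
    identity_summary(aligned, partition)$within_minus_between
  }
}

#' Null distribution of a permutation statistic
#'
#' For each replicate `b`, shuffles one group's columns (seed `seed + b`),
#' realigns the pooled set with [progressive_align()] and recomputes the
#' statistic: `"tree_length"` is the sum of branch lengths of the ML tree
#' of all sequences under an LG model; `"identity_diff"` is the
#' within-group minus between-group average identity.
#'
#' @param seqs aligned named character vector (the observed alignment).
#' @param partition two-group partition of the identifiers.
#' @param statistic `"tree_length"` or `"identity_diff"`.
#' @param B number of null replicates.
#' @param seed base seed; replicate `b` uses `seed + b`.
#' @param shuffle_group which group to shuffle (index or name; default the
#'   first).
#' @param tree_search `"nj"` (ML branch lengths on a neighbour-joining
#'   topology; the desk-scale default) or `"nni"` (full NNI search).
#' @return numeric vector of length `B`.
#' @export
null_distribution <- function(seqs, partition, statistic = c("tree_length",
                              "identity_diff"), B = 100, seed = NULL,
                              shuffle_group = 1L, tree_search = c("nj", "nni")) {
  statistic <- match.arg(statistic)
  tree_search <- match.arg(tree_search)
  stopifnot(B >= 1)
  assert_partition(partition, names(seqs))
  group <- partition[[shuffle_group]]
  vapply(seq_len(B), function(b) {
    shuf <- shuffle_group_columns(seqs, group,
                                  seed = if (is.null(seed)) NULL else seed + b)
    .perm_statistic(progressive_align(shuf), partition, statistic, tree_search)
  }, numeric(1))
}

#' Empirical permutation p-value (lower tail, add-one corrected)
#'
#' `p = (1 + #(null <= observed)) / (1 + B)`: the count of null replicates
#' with a value as low as the observed one, with the add-one correction
#' that keeps p away from zero for a finite null sample.
#'
#' @param observed observed statistic.
#' @param null_sample numeric vector of null replicates.
#' @export
permutation_pvalue <- function(observed, null_sample) {
  stopifnot(length(null_sample) >= 1)
  (1 + sum(null_sample <= observed)) / (1 + length(null_sample))
}

#' Run the column-permutation test of common ancestry
#'
#' Aligns the input, computes the observed statistic, builds its null
#' distribution by shuffling one group's columns and realigning, and
#' reports the lower-tail empirical p-value: sequences sharing ancestry
#' have lower tree lengths and lower identity differences than their
#' shuffled (origin-destroying) counterparts.
#'
#' @param seqs unaligned named character vector.
#' @inheritParams null_distribution
#' @return object of class `"perm_uca_test"` with `observed`,
#'   `null_sample` and `p_value`.
#' @export
run_permutation_test <- function(seqs, partition,
                                 statistic = c("tree_length", "identity_diff"),
                                 B = 100, seed = NULL, shuffle_group = 1L,
                                 tree_search = c("nj", "nni")) {
  statistic <- match.arg(statistic)
  tree_search <- match.arg(tree_search)
  assert_partition(partition, names(seqs))
  if (length(partition) != 2) stop("the permutation test needs 2 groups")
  aligned <- progressive_align(strip_gaps(seqs))
  observed <- .perm_statistic(aligned, partition, statistic, tree_search)
  nulls <- null_distribution(aligned, partition, statistic, B, seed,
                             shuffle_group, tree_search)
  structure(list(statistic = statistic, observed = observed,
                 null_sample = nulls,
                 p_value = permutation_pvalue(observed, nulls),
                 B = B, seed = seed),
            class = "perm_uca_test")
}

#' @export
print.perm_uca_test <- function(x, ...) {
  cat("Column-permutation test of common ancestry\n")
  cat(sprintf("  statistic: %s; observed = %.4f\n", x$statistic, x$observed))
  cat(sprintf("  null sample: B = %d, range [%.4f, %.4f]\n",
              x$B, min(x$null_sample), max(x$null_sample)))
  cat(sprintf("  p-value (lower tail) = %.4f\n", x$p_value))
  invisible(x)
}
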