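# Small shared helpers: seeded evaluation and group partitions.

# Evaluate code under a temporary RNG seed, restoring the caller's RNG
# state afterwards.  seed = NULL leaves the RNG stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Validate a group partition
#'
#' A partition is a named list of non-empty, disjoint identifier vectors;
#' when `ids` is supplied the union must equal `ids` exactly.
#'
#' @param partition named list of character vectors.
#' @param ids optional full identifier set the partition must cover.
#' @export
assert_partition <- function(partition, ids = NULL) {
  if (!is.list(partition) || length(partition) == 0)
    stop("partition must be a non-empty list of identifier vectors")
  if (is.null(names(partition)) || any(names(partition) == ""))
    names(partition) <- paste0("group", seq_along(partition))
  all_ids <- unlist(partition, use.names = FALSE)
  if (any(vapply(partition, length, 1L) == 0))
    stop("partition groups must be non-empty")
  if (anyDuplicated(all_ids))
    stop("partition groups must be disjoint")
  if (!is.null(ids)) {
    if (!setequal(all_ids, ids))
      stop("partition must cover exactly the sequence identifiers")
  }
  invisible(partition)
}

# group label of each identifier
group_of <- function(partition, ids) {
  assert_partition(partition)
  if (is.null(names(partition)))
    names(partition) <- paste0("group", seq_along(partition))
  lab <- rep(NA_character_, length(ids))
  for (g in names(partition)) lab[ids %in% partition[[g]]] <- g
  if (anyNA(lab)) stop("identifiers missing from partition: ",
                       paste(ids[is.na(lab)], collapse = ","))
  lab
}
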