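# The model-selection test of common ancestry: one tree for all sequences
# (UCA) against independent trees per group (IO), compared by AIC/BIC on a
# shared alignment, plus the separate-alignments variant where each
# hypothesis aligns its own data.

#' Akaike information criterion
#' @param lnl maximized log-likelihood.
#' @param k number of free parameters.
#' @export
aic <- function(lnl, k) 2 * k - 2 * lnl

#' Bayesian information criterion, `k log(N) - 2 LnL`
#' @inheritParams aic
#' @param n number of data points (alignment columns).
#' @export
bic <- function(lnl, k, n) {
  stopifnot(n >= 1)
  k * log(n) - 2 * lnl
}

# Fit one hypothesis group: model selection over `models` on one topology.
# Strategy "fast" follows the fixed-topology convention of the standard
# model-selection tools: one topology per group (exhaustive search under a
# reference model for <= 5 taxa, a plain neighbour-joining topology from
# capped ML distances above that -- an NNI search would let a large single
# tree mine chance similarity structure on saturated data that the smaller
# per-group fits cannot match), every candidate model rescored on it by
# full branch-length/parameter re-optimization.  "full" runs an
# independent tree search under every model.
.fit_group <- function(seqs, models, search = "fast",
                       frequencies_override = NULL) {
  # canonical identifier order: NJ tie-breaking on saturated distance
  # matrices depends on taxon order, so fits are made order-invariant by
  # sorting (the likelihood itself never depends on row order)
  d <- seqs_to_phydat(seqs[order(names(seqs))])
  if (search == "full") {
    fits <- lapply(models, function(mn) ml_tree(d, mn))
  } else {
    ref_fit <- NULL
    if (length(d) <= 5) {
      ref <- if ("LG" %in% models) "LG" else models[[1]]
      ref_fit <- ml_tree(d, ref)
      topo <- ref_fit$tree
    } else {
      ref <- NA_character_
      topo <- nj_tree(ml_distances(d))
    }
    fits <- lapply(models, function(mn) {
      if (identical(mn, ref)) ref_fit else .fit_on_tree(d, topo, mn)
    })
  }
  if (!is.null(frequencies_override)) {
    # refit +F models with externally pooled frequencies
    fits <- lapply(seq_along(fits), function(i) {
      mn <- models[[i]]
      m <- substitution_model(mn)
      if (!m$plus_f) return(fits[[i]])
      f <- fits[[i]]
      mm <- substitution_model(mn, frequencies = frequencies_override,
                               alpha = f$alpha, p_inv = f$p_inv)
      f$logLik <- log_likelihood(d, f$tree, mm)
      f$frequencies <- frequencies_override
      f
    })
  }
  tab <- data.frame(
    model = vapply(fits, `[[`, "", "model_name"),
    logLik = vapply(fits, `[[`, 0, "logLik"),
    k = vapply(fits, `[[`, 0L, "k"),
    stringsAsFactors = FALSE)
  tab$AIC <- aic(tab$logLik, tab$k)
  tab$BIC <- bic(tab$logLik, tab$k, fits[[1]]$n_sites)
  best <- which.min(tab$AIC)
  list(best = fits[[best]], table = tab,
       logLik = tab$logLik[best], k = tab$k[best],
       AIC = tab$AIC[best], BIC = tab$BIC[best],
       n_sites = fits[[best]]$n_sites,
       model = tab$model[best],
       saturated = fits[[best]]$saturated)
}

#' Fit the best model for one hypothesis
#'
#' With a single-group partition (or `partition = NULL`) this is the
#' common-ancestry fit: a tree over all sequences, best model by AIC.  With
#' two or more groups it is the independent-origins fit: each group's rows
#' are taken from the shared alignment (columns kept, so the data size N is
#' identical across hypotheses), each group runs its own model selection,
#' and the hypothesis totals are the sums of the group log-likelihoods,
#' parameter counts and information criteria.
#'
#' @param seqs aligned named character vector.
#' @param partition `NULL` or a named list of identifier groups.
#' @param models model names offered to selection.
#' @param search `"fast"` (one reference-model topology per group, all
#'   models rescored on it) or `"full"` (a tree search per model).
#' @param force_homogeneous use the pooled empirical frequencies for the
#'   `+F` models of every group and force a single shared model choice
#'   across groups (the misspecification-isolation check).
#' @return list with per-group fits and hypothesis totals `logLik`, `k`,
#'   `AIC`, `BIC`, `n_sites`.
#' @export
fit_hypothesis <- function(seqs, partition = NULL,
                           models = default_model_set(),
                           search = c("fast", "full"),
                           force_homogeneous = FALSE) {
  search <- match.arg(search)
  assert_seqs(seqs, aligned = TRUE)
  if (is.null(partition)) partition <- list(all = names(seqs))
  assert_partition(partition, names(seqs))
  if (any(vapply(partition, length, 1L) < 2))
    stop("each group needs at least 2 sequences")
  freq_override <- if (force_homogeneous && length(partition) > 1)
    empirical_frequencies(seqs) else NULL
  groups <- lapply(partition, function(ids)
    .fit_group(seqs[ids], models, search, freq_override))
  if (force_homogeneous && length(partition) > 1) {
    # one shared model name: minimize the summed AIC over a common choice
    tot <- Reduce(`+`, lapply(groups, function(g) g$table$AIC))
    pick <- which.min(tot)
    groups <- lapply(groups, function(g) {
      g$logLik <- g$table$logLik[pick]; g$k <- g$table$k[pick]
      g$AIC <- g$table$AIC[pick]; g$BIC <- g$table$BIC[pick]
      g$model <- g$table$model[pick]
      g
    })
  }
  list(groups = groups,
       logLik = sum(vapply(groups, `[[`, 0, "logLik")),
       k = sum(vapply(groups, `[[`, 0L, "k")),
       AIC = sum(vapply(groups, `[[`, 0, "AIC")),
       BIC = sum(vapply(groups, `[[`, 0, "BIC")),
       n_sites = groups[[1]]$n_sites,
       model = vapply(groups, `[[`, "", "model"),
       saturated = any(vapply(groups, `[[`, TRUE, "saturated")))
}

.classify_delta <- function(delta_aic) {
  if (delta_aic > 10) "strong-UCA"
  else if (delta_aic > 0) "weak-UCA"
  else "favours-IO"
}

#' The AIC model-selection test of common ancestry
#'
#' Fits the common-ancestry hypothesis (one tree for all sequences) and the
#' independent-origins hypothesis (separate trees per group) on the same
#' alignment and reports `delta_aic = AIC(IO) - AIC(UCA)`: positive values
#' favour common ancestry, and a difference above 10 is conventionally read
#' as essentially no support for the losing hypothesis.
#'
#' @inheritParams fit_hypothesis
#' @param partition named list of >= 2 identifier groups (the putative
#'   independent origins).  A single-group partition degenerates to
#'   `delta_aic = 0`.
#' @return object of class `"uca_test"` with the two hypothesis fits,
#'   `delta_aic`, `delta_bic` and a `classification`.
#' @export
uca_test <- function(seqs, partition, models = default_model_set(),
                     search = c("fast", "full"), force_homogeneous = FALSE) {
  search <- match.arg(search)
  assert_seqs(seqs, aligned = TRUE)
  assert_partition(partition, names(seqs))
  uca <- fit_hypothesis(seqs, NULL, models, search)
  io <- if (length(partition) == 1) uca
        else fit_hypothesis(seqs, partition, models, search, force_homogeneous)
  delta_aic <- io$AIC - uca$AIC
  delta_bic <- io$BIC - uca$BIC
  structure(list(uca = uca, io = io, partition = partition,
                 models = models,
                 delta_aic = delta_aic, delta_bic = delta_bic,
                 n_sites = uca$n_sites,
                 classification = .classify_delta(delta_aic)),
            class = "uca_test")
}

#' @export
print.uca_test <- function(x, ...) {
  cat("Model-selection test of common ancestry\n")
  cat(sprintf("  N = %d alignment columns; groups: %s\n", x$n_sites,
              paste(names(x$partition), collapse = ", ")))
  cat(sprintf("  UCA: model %s, LnL = %.2f, k = %d, AIC = %.2f\n",
              paste(x$uca$model, collapse = "/"), x$uca$logLik, x$uca$k,
              x$uca$AIC))
  cat(sprintf("  IO : model %s, LnL = %.2f, k = %d, AIC = %.2f\n",
              paste(x$io$model, collapse = "/"), x$io$logLik, x$io$k,
              x$io$AIC))
  cat(sprintf("  delta AIC (IO - UCA) = %.2f, delta BIC = %.2f -> %s\n",
              x$delta_aic, x$delta_bic, x$classification))
  if (x$uca$saturated)
    cat("  note: UCA fit contains saturated (capped) branch lengths\n")
  invisible(x)
}

#' Separate-alignments variant of the ancestry test
#'
#' Each group is aligned on its own and fitted; the pooled sequence set is
#' aligned jointly and fitted; the information-criterion difference
#' `sum(IC(group)) - IC(joint)` is scaled by the joint alignment length.
#' Because the two hypotheses are evaluated on different alignments, the
#' result is a descriptive cross-alignment comparison with no probabilistic
#' interpretation (`comparable = FALSE`).
#'
#' @param groups_unaligned named list (>= 2 entries) of ungapped sequence
#'   sets, one per group.
#' @inheritParams fit_hypothesis
#' @return object of class `"uca_sep_test"` with per-group and joint fits,
#'   `delta_aic_per_site`, `delta_bic_per_site` (positive favours UCA) and
#'   the joint/separate `length_ratio`.
#' @export
uca_test_separate <- function(groups_unaligned, models = default_model_set(),
                              search = c("fast", "full")) {
  search <- match.arg(search)
  stopifnot(is.list(groups_unaligned), length(groups_unaligned) >= 2)
  aligned <- lapply(groups_unaligned, progressive_align)
  fits <- lapply(aligned, function(a) .fit_group(a, models, search))
  pooled <- do.call(c, unname(groups_unaligned))
  joint_aln <- progressive_align(pooled)
  joint <- .fit_group(joint_aln, models, search)
  n_joint <- joint$n_sites
  sep_len <- vapply(fits, `[[`, 0L, "n_sites")
  structure(list(
    group_fits = fits, joint_fit = joint,
    group_lengths = sep_len, joint_length = n_joint,
    length_ratio = n_joint / mean(sep_len),
    delta_aic_per_site = (sum(vapply(fits, `[[`, 0, "AIC")) - joint$AIC) / n_joint,
    delta_bic_per_site = (sum(vapply(fits, `[[`, 0, "BIC")) - joint$BIC) / n_joint,
    comparable = FALSE),
    class = "uca_sep_test")
}

#' @export
print.uca_sep_test <- function(x, ...) {
  cat("Separate-alignments ancestry comparison",
      "(cross-alignment; no probabilistic interpretation)\n")
  cat(sprintf("  separate lengths: %s; joint length: %d (ratio %.3f)\n",
              paste(x$group_lengths, collapse = ", "), x$joint_length,
              x$length_ratio))
  cat(sprintf("  scaled delta AIC = %.4f per site, delta BIC = %.4f per site\n",
              x$delta_aic_per_site, x$delta_bic_per_site))
  cat("  (positive values favour common ancestry)\n")
  invisible(x)
}
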