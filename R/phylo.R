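# Maximum-likelihood engine: pruning log-likelihood, branch-length and
# model-parameter optimization, small-scale topology search, tree length.
# The numerical core is phangorn's pml/optim.pml; this layer fixes the
# model conventions (empirical +F frequencies by counting, gamma shape and
# invariant-proportion handling, saturation flags) used by the ancestry
# tests.

# phangorn's optim.pml bounds branch lengths at 10 (computationally
# stationary at the data sizes used here).
.edge_cap <- 10

#' Empirical amino-acid frequencies of an alignment
#'
#' Counting frequencies (gaps excluded), floored at `1e-6` and
#' renormalized -- the `+F` convention of common model-selection tools.
#'
#' @param seqs aligned named character vector (or a `phyDat` object).
#' @export
empirical_frequencies <- function(seqs) {
  d <- if (inherits(seqs, "phyDat")) seqs else seqs_to_phydat(seqs)
  bf <- phangorn::baseFreq(d)
  bf <- pmax(bf, 1e-6)
  bf <- bf / sum(bf)
  names(bf) <- .aa
  bf
}

# Map a model (name or substitution_model) onto pml arguments.  For fits,
# +F frequencies come from the data; for likelihood-only evaluation of a
# concrete substitution_model its own frequencies are used.
.model_spec <- function(model, data = NULL) {
  if (is.character(model)) model <- substitution_model(model)
  stopifnot(inherits(model, "substitution_model"))
  bf <- if (model$plus_f && !is.null(data)) {
    empirical_frequencies(data)
  } else model$frequencies
  list(model = model,
       Q = model$exchangeabilities[lower.tri(model$exchangeabilities)],
       bf = as.numeric(bf),
       k = model$n_categories,
       shape = if (is.null(model$alpha)) 1 else model$alpha,
       inv = if (is.null(model$p_inv)) 0 else model$p_inv)
}

# fraction of alignment columns compatible with being invariant
.constant_fraction <- function(d) {
  m <- as.character(d)
  const <- apply(m, 2, function(x) {
    x <- x[x %in% .aa]
    length(x) == 0 || length(unique(x)) == 1
  })
  mean(const)
}

.n_columns <- function(d) length(attr(d, "index"))

#' Pruning log-likelihood of an alignment on a tree
#'
#' Felsenstein-pruning log-likelihood over compressed site patterns, with
#' gap characters treated as missing data (marginalized).
#'
#' @param seqs aligned named character vector whose identifiers match the
#'   tree's tip labels.
#' @param tree ape `phylo` tree with branch lengths.
#' @param model a [substitution_model()] (its own frequencies, shape and
#'   invariant proportion are used) or a model name (then `+F` frequencies
#'   are counted from the data).
#' @return log-likelihood (numeric scalar).
#' @export
log_likelihood <- function(seqs, tree, model) {
  d <- if (inherits(seqs, "phyDat")) seqs else seqs_to_phydat(seqs)
  if (!setequal(names(d), tree$tip.label))
    stop("alignment identifiers must match tree tip labels")
  sp <- .model_spec(model, data = if (is.character(model)) d else NULL)
  fit <- phangorn::pml(tree, d, bf = sp$bf, Q = sp$Q, k = sp$k,
                       shape = sp$shape, inv = sp$inv)
  as.numeric(fit$logLik)
}

# Outer-loop tolerance 1e-5 log-likelihood units over at most 5 sweeps:
# fits enter AIC/BIC differences of order 10+, so tighter optimization
# buys nothing at these data sizes.
.optim_quiet <- function(fit, ...) {
  out <- try(suppressWarnings(
    phangorn::optim.pml(fit, ...,
                        control = phangorn::pml.control(trace = 0,
                                                        epsilon = 1e-5,
                                                        maxit = 5))),
    silent = TRUE)
  if (inherits(out, "try-error")) fit else out
}

# Direct optimization of a 2-taxon fit: phangorn's edge optimizer does not
# handle the single-branch case, so optimize the (only identifiable) total
# length by golden-section search, with gamma/inv profiled by optim.pml.
.optim_two_taxa <- function(fit, opt_gamma, opt_inv) {
  obj <- function(t) {
    tr <- fit$tree
    tr$edge.length <- rep(t / length(tr$edge.length), length(tr$edge.length))
    -stats::update(fit, tree = tr)$logLik
  }
  opt <- stats::optimize(obj, c(1e-8, .edge_cap), tol = 1e-8)
  tr <- fit$tree
  tr$edge.length <- rep(opt$minimum / length(tr$edge.length),
                        length(tr$edge.length))
  fit <- stats::update(fit, tree = tr)
  if (opt_gamma || opt_inv)
    fit <- .optim_quiet(fit, optEdge = FALSE, optGamma = opt_gamma,
                        optInv = opt_inv, optBf = FALSE, optQ = FALSE)
  fit
}

# Core fitting routine shared by fit_phylo/ml_tree.
.fit_on_tree <- function(d, tree, model_name, opt_nni = FALSE) {
  sp <- .model_spec(model_name, data = d)
  m <- sp$model
  tree$edge.length[tree$edge.length < 1e-8] <- 1e-8
  tree$edge.length[tree$edge.length > .edge_cap] <- .edge_cap
  opt_inv <- !is.null(m$p_inv) && .constant_fraction(d) > 0
  inv0 <- if (is.null(m$p_inv)) 0 else if (opt_inv) max(m$p_inv, 0.01) else 0
  fit <- phangorn::pml(tree, d, bf = sp$bf, Q = sp$Q, k = sp$k,
                       shape = if (is.null(m$alpha)) 1 else m$alpha,
                       inv = inv0)
  fit <- if (length(d) == 2) {
    .optim_two_taxa(fit, !is.null(m$alpha), opt_inv)
  } else {
    .optim_quiet(fit, optEdge = TRUE, optNni = opt_nni,
                 optGamma = !is.null(m$alpha), optInv = opt_inv,
                 optBf = FALSE, optQ = FALSE)
  }
  structure(
    list(model_name = m$name,
         tree = fit$tree,
         logLik = as.numeric(fit$logLik),
         k = parameter_count(m) + nrow(fit$tree$edge),
         n_sites = .n_columns(d),
         frequencies = stats::setNames(fit$bf, .aa),
         alpha = if (!is.null(m$alpha)) fit$shape else NULL,
         p_inv = if (!is.null(m$p_inv)) fit$inv else NULL,
         saturated = .is_saturated(fit)),
    class = "phylo_fit")
}

# A fit is saturated when the data cannot reject infinite branch lengths:
# pushing every long branch to the upper bound costs less than half the 5%
# chi-square(1) quantile in log-likelihood units, i.e. a likelihood-ratio
# test cannot reject t = Inf.  (The optimizer may stop anywhere inside the
# flat region, so the fitted value itself is not a reliable indicator.)
.is_saturated <- function(fit, long = 2, tol = stats::qchisq(0.95, 1) / 2) {
  idx <- fit$tree$edge.length > long
  if (!any(idx)) return(FALSE)
  tr <- fit$tree
  tr$edge.length[idx] <- .edge_cap
  capped <- try(stats::update(fit, tree = tr)$logLik, silent = TRUE)
  if (inherits(capped, "try-error")) return(FALSE)
  as.numeric(capped) > as.numeric(fit$logLik) - tol
}

#' Fit a substitution model on a fixed tree topology
#'
#' Optimizes branch lengths and the model's free parameters (gamma shape,
#' invariant proportion) by maximum likelihood; `+F` frequencies are set to
#' the empirical counting frequencies, not iteratively optimized.
#'
#' @param seqs aligned named character vector.
#' @param tree starting tree (its topology is kept).
#' @param model model name (see [substitution_model()]).
#' @return object of class `"phylo_fit"`: optimized tree, `logLik`,
#'   free-parameter count `k` (model parameters plus branch lengths),
#'   alignment width `n_sites`, and a `saturated` flag marking fits with a
#'   branch at the upper bound.
#' @export
fit_phylo <- function(seqs, tree, model) {
  d <- if (inherits(seqs, "phyDat")) seqs else seqs_to_phydat(seqs)
  if (!setequal(names(d), tree$tip.label))
    stop("alignment identifiers must match tree tip labels")
  .fit_on_tree(d, tree, model)
}

#' @export
print.phylo_fit <- function(x, ...) {
  cat("ML fit:", x$model_name, "\n")
  cat(sprintf("  logLik = %.3f, k = %d, N = %d columns\n",
              x$logLik, x$k, x$n_sites))
  if (!is.null(x$alpha)) cat(sprintf("  alpha = %.3f\n", x$alpha))
  if (!is.null(x$p_inv)) cat(sprintf("  p_inv = %.3f\n", x$p_inv))
  cat("  tree length =", format(tree_length(x$tree)),
      if (x$saturated) "(saturated branches)" else "", "\n")
  invisible(x)
}

#' @export
logLik.phylo_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n_sites,
            class = "logLik")
}

#' Optimize branch lengths only
#' @inheritParams fit_phylo
#' @return the tree with ML branch lengths (log-likelihood as attribute).
#' @export
optimize_branch_lengths <- function(seqs, tree, model) {
  d <- if (inherits(seqs, "phyDat")) seqs else seqs_to_phydat(seqs)
  sp <- .model_spec(model, data = d)
  m <- sp$model
  tree$edge.length[tree$edge.length < 1e-8] <- 1e-8
  tree$edge.length[tree$edge.length > .edge_cap] <- .edge_cap
  fit <- phangorn::pml(tree, d, bf = sp$bf, Q = sp$Q, k = sp$k,
                       shape = if (is.null(m$alpha)) 1 else m$alpha,
                       inv = if (is.null(m$p_inv)) 0 else m$p_inv)
  fit <- if (length(d) == 2) .optim_two_taxa(fit, FALSE, FALSE)
         else .optim_quiet(fit, optEdge = TRUE)
  out <- fit$tree
  attr(out, "logLik") <- as.numeric(fit$logLik)
  out
}

#' Model-corrected pairwise ML distances, capped
#' @param seqs aligned named character vector.
#' @param cap maximum distance (default 10).
#' @export
ml_distances <- function(seqs, cap = .edge_cap) {
  d <- if (inherits(seqs, "phyDat")) seqs else seqs_to_phydat(seqs)
  dm <- as.matrix(phangorn::dist.ml(d, model = "LG"))
  dm[!is.finite(dm) | dm > cap] <- cap
  dm
}

#' Neighbour-joining tree from a distance matrix
#' @param distances symmetric distance matrix with labelled rows.
#' @export
nj_tree <- function(distances) {
  ape::nj(stats::as.dist(distances))
}

#' Maximum-likelihood tree under one model
#'
#' Exhaustive search over all unrooted topologies for up to 5 taxa (3
#' topologies for a quartet); for larger sets, a neighbour-joining start
#' from capped ML distances followed by NNI hill climbing.
#'
#' @inheritParams fit_phylo
#' @return `"phylo_fit"` of the best topology found.
#' @export
ml_tree <- function(seqs, model) {
  d <- if (inherits(seqs, "phyDat")) seqs else seqs_to_phydat(seqs)
  n <- length(d)
  if (n < 2) stop("need at least 2 sequences")
  if (n == 2) {
    tr <- read_newick(sprintf("(%s:0.1,%s:0.1);", names(d)[1], names(d)[2]))
    return(.fit_on_tree(d, tr, model))
  }
  if (n <= 5) {
    cands <- phangorn::allTrees(n, rooted = FALSE, tip.label = names(d))
    fits <- lapply(cands, function(tr) {
      tr$edge.length <- rep(0.1, nrow(tr$edge))
      .fit_on_tree(d, tr, model)
    })
    return(fits[[which.max(vapply(fits, `[[`, 0, "logLik"))]])
  }
  start <- nj_tree(ml_distances(d))
  .fit_on_tree(d, start, model, opt_nni = TRUE)
}

#' Sum of branch lengths of a tree
#' @param tree ape `phylo` object.
#' @export
tree_length <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) return(0)
  sum(tree$edge.length)
}
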