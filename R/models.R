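# Amino-acid substitution models: named model construction, closed-form
# Poisson transition probabilities, GTR-form rate matrices and their
# matrix exponentials, discrete-gamma rate categories.

#' The twenty amino-acid one-letter codes, in the conventional
#' A, R, N, ... V ordering used throughout the package.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

.aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Expand phangorn's lower-triangle (column-major) exchangeability vector
# into a full symmetric 20x20 matrix with zero diagonal.
.expand_exchangeabilities <- function(q190) {
  s <- matrix(0, 20, 20, dimnames = list(.aa, .aa))
  s[lower.tri(s)] <- q190
  s + t(s)
}

.lg_params <- function() {
  lg <- get(".LG", envir = asNamespace("phangorn"))
  bf <- as.numeric(lg$bf)
  names(bf) <- .aa
  list(exchangeabilities = .expand_exchangeabilities(lg$Q), frequencies = bf)
}

#' Construct a named amino-acid substitution model
#'
#' Supported model names are `"Poisson"`, `"Poisson+F"`, `"LG"`, `"LG+G"`,
#' `"LG+I+G"` and `"LG+I+G+F"` (components may appear in any order after the
#' base name).  The Poisson model has all exchangeabilities equal; `LG` uses
#' the Le-Gascuel empirical replacement matrix.  `+F` marks the equilibrium
#' frequencies as free (estimated from data when fitting, supplied when
#' simulating); without it Poisson uses uniform frequencies and LG its
#' published frequencies.  `+G` adds discrete-gamma rate heterogeneity with
#' shape `alpha`, `+I` a proportion `p_inv` of invariant sites.
#'
#' @param name model name string, e.g. `"LG+I+G+F"`.
#' @param frequencies optional length-20 frequency vector (must sum to 1);
#'   used as the simulation/starting frequencies for `+F` models.
#' @param alpha gamma shape parameter (used when the model has `+G`).
#' @param p_inv proportion of invariant sites in `[0, 1)` (used with `+I`).
#' @param n_categories number of discrete gamma categories (default 4).
#' @return an object of class `"substitution_model"`.
#' @export
substitution_model <- function(name, frequencies = NULL, alpha = NULL,
                               p_inv = NULL, n_categories = 4L) {
  parts <- strsplit(name, "+", fixed = TRUE)[[1]]
  base <- parts[1]
  flags <- parts[-1]
  if (!base %in% c("Poisson", "LG"))
    stop("unknown base model: ", base)
  if (length(setdiff(flags, c("F", "G", "I"))) > 0)
    stop("unknown model component in: ", name)
  plus_f <- "F" %in% flags
  plus_g <- "G" %in% flags
  plus_i <- "I" %in% flags

  if (base == "Poisson") {
    exch <- matrix(1, 20, 20, dimnames = list(.aa, .aa))
    diag(exch) <- 0
    base_freq <- rep(1 / 20, 20)
    names(base_freq) <- .aa
  } else {
    lg <- .lg_params()
    exch <- lg$exchangeabilities
    base_freq <- lg$frequencies
  }

  if (!is.null(frequencies)) {
    stopifnot(length(frequencies) == 20, all(frequencies > 0))
    if (abs(sum(frequencies) - 1) > 1e-12)
      stop("frequencies must sum to 1")
    freq <- as.numeric(frequencies)
    names(freq) <- .aa
  } else {
    freq <- base_freq
  }
  if (plus_g) {
    if (is.null(alpha)) alpha <- 1
    stopifnot(alpha > 0)
  } else alpha <- NULL
  if (plus_i) {
    if (is.null(p_inv)) p_inv <- 0
    stopifnot(p_inv >= 0, p_inv < 1)
  } else p_inv <- NULL

  structure(
    list(name = name, base = base, plus_f = plus_f,
         exchangeabilities = exch, frequencies = freq,
         alpha = alpha, p_inv = p_inv,
         n_categories = if (!is.null(alpha)) as.integer(n_categories) else 1L),
    class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("Amino-acid substitution model:", x$name, "\n")
  cat("  exchangeabilities:", if (x$base == "Poisson") "equal" else x$base, "\n")
  cat("  frequencies:",
      if (x$plus_f) "free (+F)" else if (x$base == "Poisson") "uniform" else "empirical",
      sprintf("[range %.4f-%.4f]", min(x$frequencies), max(x$frequencies)), "\n")
  if (!is.null(x$alpha))
    cat(sprintf("  gamma shape alpha = %.3f (%d categories)\n",
                x$alpha, x$n_categories))
  if (!is.null(x$p_inv))
    cat(sprintf("  invariant proportion p_inv = %.3f\n", x$p_inv))
  invisible(x)
}

#' Closed-form Poisson transition probability
#'
#' Probability of observing state `b` at the end of a branch of length `t`
#' that started in state `a`, under the frequency-weighted Poisson process
#' whose jump chain lands on state `x` with probability `pi_x`:
#' `P(b | a, t) = exp(-t) [a == b] + (1 - exp(-t)) pi_b`.
#' Time is measured in expected jumps per site (the generator
#' `Q = 1 pi' - I`), not in expected substitutions; the two scales differ by
#' the factor `1 - sum(pi^2)`.  `t = Inf` is allowed and gives `pi_b`: the
#' end state is then independent of the start state, which is what makes a
#' star tree with unbounded branches equivalent to independent origins.
#'
#' @param a,b initial and final states (one-letter codes or indices 1..20).
#' @param t branch length, non-negative (may be `Inf`).
#' @param frequencies equilibrium frequency vector `pi`.
#' @return a probability.
#' @export
poisson_transition <- function(a, b, t, frequencies) {
  stopifnot(length(frequencies) == 20, abs(sum(frequencies) - 1) < 1e-9)
  if (any(t < 0)) stop("negative branch length")
  ai <- .state_index(a)
  bi <- .state_index(b)
  exp(-t) * (ai == bi) + (1 - exp(-t)) * frequencies[bi]
}

#' Joint probability of a two-sequence site pattern
#'
#' Probability of observing states `a` and `b` at one site of two sequences
#' separated by total path length `t` under the Poisson model at
#' stationarity: `exp(-t) pi_a + pi_a^2 (1 - exp(-t))` for the same-state
#' case and `pi_a pi_b (1 - exp(-t))` otherwise.  At `t = Inf` these reduce
#' to `pi_a^2` and `pi_a pi_b`, the profile-sampling probabilities.
#'
#' @inheritParams poisson_transition
#' @export
pair_joint_probability <- function(a, b, t, frequencies) {
  stopifnot(length(frequencies) == 20, abs(sum(frequencies) - 1) < 1e-9)
  if (any(t < 0)) stop("negative branch length")
  ai <- .state_index(a)
  bi <- .state_index(b)
  pa <- frequencies[ai]
  pb <- frequencies[bi]
  ifelse(ai == bi, exp(-t) * pa + pa^2 * (1 - exp(-t)),
         pa * pb * (1 - exp(-t)))
}

.state_index <- function(x) {
  if (is.character(x)) {
    i <- match(toupper(x), .aa)
    if (anyNA(i)) stop("unknown amino-acid state: ", paste(x[is.na(i)], collapse = ","))
    i
  } else {
    stopifnot(all(x >= 1), all(x <= 20))
    as.integer(x)
  }
}

#' Instantaneous rate matrix of a substitution model
#'
#' GTR-form construction `Q[a, b] = s[a, b] * pi[b]` for `a != b`, diagonal
#' set so rows sum to zero.  With `normalize = TRUE` (default) the matrix is
#' rescaled so the mean rate at stationarity, `-sum(pi * diag(Q))`, equals 1
#' and branch lengths are expected substitutions per site.  With
#' `normalize = FALSE` the Poisson model yields the jump-chain generator
#' `Q = 1 pi' - I` whose exponential is exactly the closed form of
#' [poisson_transition()].
#'
#' @param model a [substitution_model()].
#' @param normalize rescale to unit mean rate?
#' @return 20x20 rate matrix with the model frequencies as attribute
#'   `"frequencies"`.
#' @export
build_rate_matrix <- function(model, normalize = TRUE) {
  stopifnot(inherits(model, "substitution_model"))
  pi <- model$frequencies
  q <- model$exchangeabilities * rep(pi, each = 20)
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  if (normalize) {
    mu <- -sum(pi * diag(q))
    q <- q / mu
  }
  attr(q, "frequencies") <- pi
  q
}

#' Transition probability matrix P(t * rate)
#'
#' Matrix exponential of a reversible rate matrix, computed through the
#' symmetrized eigendecomposition.  Effective lengths `t * rate >= 1e4` are
#' short-circuited to the stationary matrix (each row equal to `pi`); they
#' are numerically stationary long before that.
#'
#' @param q rate matrix from [build_rate_matrix()].
#' @param t branch length (non-negative, finite or `Inf`).
#' @param rate rate multiplier (e.g. a gamma category rate).
#' @return 20x20 stochastic matrix.
#' @export
transition_matrix <- function(q, t, rate = 1) {
  if (t < 0 || rate < 0) stop("negative branch length or rate")
  pi <- attr(q, "frequencies")
  if (is.null(pi)) stop("rate matrix lacks a frequencies attribute")
  tt <- t * rate
  if (tt == 0) {
    p <- diag(20)
    dimnames(p) <- dimnames(q)
    return(p)
  }
  if (tt >= 1e4) {
    p <- matrix(pi, 20, 20, byrow = TRUE, dimnames = dimnames(q))
    return(p)
  }
  ed <- .q_eigen(q, pi)
  p <- ed$right %*% (exp(tt * ed$values) * ed$left)
  p[p < 0] <- 0
  p <- p / rowSums(p)
  dimnames(p) <- dimnames(q)
  p
}

# Eigendecomposition of a reversible Q via the symmetric matrix
# D^(1/2) Q D^(-1/2); cached on the matrix would be overkill at 20x20.
.q_eigen <- function(q, pi) {
  d <- sqrt(pi)
  b <- q * (d %o% (1 / d))
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  list(values = e$values,
       right = (1 / d) * e$vectors,
       left = t(e$vectors * d))
}

#' Discrete-gamma rate categories
#'
#' Standard equal-weight discretization of the mean-1 gamma distribution
#' (shape and rate both `alpha`): categories are the K equal-probability
#' quantile bins, each represented by its conditional mean, so the overall
#' mean rate is exactly 1.
#'
#' @param alpha gamma shape (> 0).
#' @param k number of categories (>= 1).
#' @return list with `rates` and `weights`, each length `k`.
#' @export
discrete_gamma <- function(alpha, k = 4L) {
  stopifnot(alpha > 0, k >= 1)
  k <- as.integer(k)
  if (k == 1L) return(list(rates = 1, weights = 1))
  breaks <- stats::qgamma((0:k) / k, shape = alpha, rate = alpha)
  # E[X; a < X < b] for Gamma(alpha, alpha) is pgamma(b, alpha+1) - pgamma(a, alpha+1)
  mass <- stats::pgamma(breaks, shape = alpha + 1, rate = alpha)
  rates <- k * diff(mass)
  rates <- rates / (mean(rates))      # exact unit mean against roundoff
  list(rates = rates, weights = rep(1 / k, k))
}

#' Site-rate categories of a model, with invariant sites folded in
#'
#' Combines the model's discrete-gamma categories with its invariant-site
#' proportion: `p_inv` becomes an extra zero-rate category and the gamma
#' rates are divided by `1 - p_inv` so the overall mean rate stays 1.
#'
#' @param model a [substitution_model()].
#' @return list with `rates` and `weights` (weights sum to 1, weighted mean
#'   rate 1).
#' @export
rate_categories <- function(model) {
  stopifnot(inherits(model, "substitution_model"))
  if (is.null(model$alpha)) {
    g <- list(rates = 1, weights = 1)
  } else {
    g <- discrete_gamma(model$alpha, model$n_categories)
  }
  p0 <- if (is.null(model$p_inv)) 0 else model$p_inv
  if (p0 > 0) {
    list(rates = c(0, g$rates / (1 - p0)),
         weights = c(p0, g$weights * (1 - p0)))
  } else g
}

#' Free-parameter count of a substitution model
#'
#' Counts the free parameters a maximum-likelihood fit of the model
#' estimates, excluding branch lengths: 19 for `+F` frequencies (the
#' simplex dimension), 1 for a gamma shape, 1 for an invariant proportion.
#' Fixed empirical exchangeabilities (LG) and the equal-exchangeability
#' Poisson matrix contribute 0.
#'
#' @param model a [substitution_model()] or model name string.
#' @return integer parameter count.
#' @export
parameter_count <- function(model) {
  if (is.character(model)) model <- substitution_model(model)
  stopifnot(inherits(model, "substitution_model"))
  19L * model$plus_f + (!is.null(model$alpha)) + (!is.null(model$p_inv))
}

#' Model names offered to model selection by default
#' @export
default_model_set <- function() {
  c("Poisson", "Poisson+F", "LG", "LG+G", "LG+I+G", "LG+I+G+F")
}
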