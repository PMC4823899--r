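# Sequence simulation under explicit common-ancestry and independent-origins
# scenarios: continuous-time substitution along a tree with optional indels
# and true-homology bookkeeping, saturated star trees, per-column profile
# sampling, and the two-quartet group scenarios.

#' Indel model: Poisson events with geometric lengths
#'
#' Rates are events per unit branch length (i.e. per expected substitution)
#' per site; fragment lengths are 1 + Geometric(q), capped at `max_length`.
#'
#' @param insertion_rate,deletion_rate non-negative event rates.
#' @param q geometric length parameter in (0, 1).
#' @param max_length cap on fragment length.
#' @export
indel_model <- function(insertion_rate = 0.03, deletion_rate = 0.03,
                        q = 0.5, max_length = 20L) {
  stopifnot(insertion_rate >= 0, deletion_rate >= 0, q > 0, q < 1,
            max_length >= 1)
  structure(list(insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate,
                 q = q, max_length = as.integer(max_length)),
            class = "indel_model")
}

#' Sample a random amino-acid frequency vector
#'
#' Twenty independent Uniform(0,1) draws normalized to sum to one; each
#' simulated data set gets its own such vector.
#'
#' @param seed optional integer seed (deterministic given the seed).
#' @return named length-20 frequency vector.
#' @export
sample_frequencies <- function(seed = NULL) {
  with_seed(seed, {
    x <- stats::runif(20)
    x <- x / sum(x)
    names(x) <- .aa
    x
  })
}

.rgeom_len <- function(n, q, max_length) {
  pmin(stats::rgeom(n, q) + 1L, max_length)
}

# Evolve one node sequence along a branch.  states: integer vector 1..20;
# keys: numeric homology keys; cats: per-site rate category index.
.evolve_branch <- function(node, t, pmats, model, rc, indels) {
  states <- node$states
  # substitutions: site-wise via the per-category transition matrices
  if (t > 0 && length(states) > 0) {
    new <- states
    for (ci in seq_along(rc$rates)) {
      if (rc$rates[ci] == 0) next
      p <- pmats[[ci]]
      sel <- which(node$cats == ci)
      for (s in unique(states[sel])) {
        idx <- sel[states[sel] == s]
        new[idx] <- sample.int(20L, length(idx), replace = TRUE, prob = p[s, ])
      }
    }
    states <- new
  }
  node$states <- states
  # indels: event times from the current-length Gillespie rate; inserted
  # fragments are stationary draws made at the event, substitutions having
  # been applied to inherited sites over the whole branch.
  if (!is.null(indels) && t > 0) {
    ir <- indels$insertion_rate
    dr <- indels$deletion_rate
    time <- 0
    repeat {
      l <- length(node$states)
      rate <- (ir + dr) * max(l, 1L)
      if (rate == 0) break
      time <- time + stats::rexp(1, rate)
      if (time > t) break
      g <- .rgeom_len(1, indels$q, indels$max_length)
      if (stats::runif(1) < ir / (ir + dr)) {
        p <- sample.int(l + 1L, 1L) - 1L            # insert after position p
        lo <- if (p == 0L) (if (l == 0L) 0 else node$keys[1] - 1) else node$keys[p]
        hi <- if (p >= l) lo + 1 else node$keys[p + 1L]
        keys <- sort(lo + stats::runif(g) * (hi - lo))
        st <- sample.int(20L, g, replace = TRUE, prob = model$frequencies)
        ct <- sample.int(length(rc$rates), g, replace = TRUE, prob = rc$weights)
        at <- seq_len(l) <= p
        node$states <- c(node$states[at], st, node$states[!at])
        node$keys <- c(node$keys[at], keys, node$keys[!at])
        node$cats <- c(node$cats[at], ct, node$cats[!at])
      } else if (l > 0) {
        p <- sample.int(l, 1L)
        drop <- p:min(p + g - 1L, l)
        node$states <- node$states[-drop]
        node$keys <- node$keys[-drop]
        node$cats <- node$cats[-drop]
      }
    }
  }
  node
}

#' Simulate sequences along a tree
#'
#' The root sequence is drawn i.i.d. from the model's equilibrium
#' frequencies; each site receives a rate category once (shared down the
#' tree); each branch applies the corresponding transition matrices, then
#' optional insertion/deletion events with true-homology bookkeeping.
#'
#' @param tree ape `phylo` tree (star and binary shapes supported).
#' @param model a [substitution_model()].
#' @param length number of root sites.
#' @param indels optional [indel_model()].
#' @param seed optional integer seed.
#' @return object of class `"sim_result"` with `true_alignment` (gapped,
#'   homology-true), `sequences` (gaps stripped), `tree`, `model`, `seed`.
#' @export
simulate_on_tree <- function(tree, model, length, indels = NULL, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), length >= 1)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  with_seed(seed, {
    q <- build_rate_matrix(model)
    rc <- rate_categories(model)
    ntip <- base::length(tree$tip.label)
    root <- list(
      states = sample.int(20L, length, replace = TRUE, prob = model$frequencies),
      keys = as.numeric(seq_len(length)),
      cats = sample.int(base::length(rc$rates), length, replace = TRUE,
                        prob = rc$weights))
    children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
    leaves <- vector("list", ntip)
    walk <- function(node_id, node) {
      kid_edges <- children[[as.character(node_id)]]
      if (is.null(kid_edges)) { leaves[[node_id]] <<- node; return(invisible()) }
      for (e in kid_edges) {
        t <- tree$edge.length[e]
        pmats <- lapply(rc$rates, function(r)
          if (r == 0) diag(20) else transition_matrix(q, t, r))
        walk(tree$edge[e, 2], .evolve_branch(node, t, pmats, model, rc, indels))
      }
    }
    walk(ntip + 1L, root)
    .sim_result(leaves, tree$tip.label, tree, model, seed)
  })
}

.sim_result <- function(leaves, labels, tree, model, seed, partition = NULL) {
  all_keys <- sort(unique(unlist(lapply(leaves, `[[`, "keys"))))
  aln <- vapply(seq_along(leaves), function(i) {
    row <- rep("-", length(all_keys))
    row[match(leaves[[i]]$keys, all_keys)] <- .aa[leaves[[i]]$states]
    paste(row, collapse = "")
  }, character(1))
  names(aln) <- labels
  structure(list(true_alignment = aln,
                 sequences = strip_gaps(aln),
                 tree = tree, model = model, seed = seed,
                 partition = partition),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Simulated sequence set:", length(x$sequences), "sequences,",
      nchar(x$true_alignment[[1]]), "true-alignment columns\n")
  if (!is.null(x$model) && inherits(x$model, "substitution_model"))
    cat("  model:", x$model$name, "\n")
  if (!is.null(x$partition))
    cat("  groups:", paste(names(x$partition), collapse = ", "), "\n")
  invisible(x)
}

.star_io_tree <- function(n, branch_length) {
  labs <- sprintf("s%d", seq_len(n))
  if (n == 8) {
    txt <- sprintf("((%s):0,(%s):0);",
                   paste(sprintf("%s:%g", labs[1:4], branch_length), collapse = ","),
                   paste(sprintf("%s:%g", labs[5:8], branch_length), collapse = ","))
  } else {
    txt <- sprintf("(%s);",
                   paste(sprintf("%s:%g", labs, branch_length), collapse = ","))
  }
  read_newick(txt)
}

#' Simulate independently originated sequences on a saturated star tree
#'
#' For 8 sequences, two quartets joined by a collapsed internal branch of
#' length zero with all terminal branches of huge length (default 2500) --
#' computationally equivalent to independently originated sequences drawn
#' from a common amino-acid pool.  The model is Poisson with a shared
#' random frequency vector.
#'
#' @param n_sequences number of sequences (default 8).
#' @param length sites (default 1000).
#' @param branch_length terminal branch length (default 2500).
#' @param seed optional integer seed.
#' @return `"sim_result"`, with `partition` splitting the set into its two
#'   putative origin groups.
#' @export
simulate_star_io <- function(n_sequences = 8L, length = 1000L,
                             branch_length = 2500, seed = NULL) {
  stopifnot(n_sequences >= 2)
  with_seed(seed, {
    pi <- sample_frequencies()
    model <- substitution_model("Poisson+F", frequencies = pi)
    tree <- .star_io_tree(n_sequences, branch_length)
    res <- simulate_on_tree(tree, model, length)
    half <- ceiling(n_sequences / 2)
    res$partition <- list(g1 = tree$tip.label[seq_len(half)],
                          g2 = tree$tip.label[(half + 1):n_sequences])
    res$seed <- seed
    res
  })
}

#' Simulate sequences under the per-column profile model
#'
#' Each alignment column is filled i.i.d. from an amino-acid frequency
#' vector: one shared vector for all columns (`"shared"`, the distribution
#' of a saturated star tree) or a fresh vector per column (`"per-site"`).
#'
#' @param n_sequences,length dimensions of the output.
#' @param seed optional integer seed.
#' @param frequency_source `"shared"` or `"per-site"`.
#' @export
simulate_profile <- function(n_sequences, length, seed = NULL,
                             frequency_source = c("shared", "per-site")) {
  frequency_source <- match.arg(frequency_source)
  stopifnot(n_sequences >= 2, length >= 1)
  with_seed(seed, {
    labs <- sprintf("s%d", seq_len(n_sequences))
    if (frequency_source == "shared") {
      pi <- sample_frequencies()
      m <- matrix(sample(.aa, n_sequences * length, replace = TRUE, prob = pi),
                  n_sequences, length)
      model <- substitution_model("Poisson+F", frequencies = pi)
    } else {
      m <- vapply(seq_len(length), function(i) {
        pii <- stats::runif(20)
        sample(.aa, n_sequences, replace = TRUE, prob = pii / sum(pii))
      }, character(n_sequences))
      if (n_sequences == 1) m <- matrix(m, 1)
      model <- NULL
    }
    rownames(m) <- labs
    aln <- matrix_to_seqs(m)
    structure(list(true_alignment = aln, sequences = aln,
                   tree = NULL, model = model, seed = seed,
                   partition = NULL),
              class = "sim_result")
  })
}

#' Default configuration of the two-quartet group scenario
#'
#' Two quartets, B and E, evolved under LG+I+G+F.  Branch lengths: B
#' terminal 0.3, internal 0.15; E terminal 0.5, internal 0.25; gamma shape
#' 1, invariant proportion 0.1.  Under independent origins the quartets
#' are simulated from independent root sequences; under common ancestry a
#' single 8-leaf tree joins them by a finite bridge (default 0.2).  By
#' default the two groups draw their states from one shared random
#' frequency vector per run (`shared_frequencies = TRUE`): as in the
#' saturated-star scenario, what makes the groups independent is their
#' ancestry, not their amino-acid composition.  Set
#' `shared_frequencies = FALSE` to give each group its own random vector
#' (a compositionally heterogeneous variant).
#'
#' @param joining_branch bridge length of the common-ancestry variant.
#' @param indels an [indel_model()] or `NULL` to disable indels.
#' @param shared_frequencies do B and E share one frequency vector?
#' @export
two_group_config <- function(joining_branch = 0.2, indels = indel_model(),
                             shared_frequencies = TRUE) {
  list(
    b = list(terminal = 0.3, internal = 0.15),
    e = list(terminal = 0.5, internal = 0.25),
    alpha = 1.0, p_inv = 0.1,
    joining_branch = joining_branch,
    indels = indels,
    shared_frequencies = shared_frequencies)
}

.quartet_tree <- function(labs, terminal, internal) {
  read_newick(sprintf("((%s:%g,%s:%g):%g,%s:%g,%s:%g);",
                      labs[1], terminal, labs[2], terminal, internal,
                      labs[3], terminal, labs[4], terminal))
}

#' Simulate the two-quartet group scenario
#'
#' @param variant `"io"` (independent roots for B and E; the pooled true
#'   alignment stacks the two group alignments side by side, padding the
#'   shorter with all-gap columns) or `"uca"` (one 8-leaf tree, one model).
#' @param length root sequence length (default 6591 sites).
#' @param seed optional integer seed.
#' @param config a [two_group_config()].
#' @return `"sim_result"` with `partition = list(B = ..., E = ...)`.
#' @export
simulate_two_groups <- function(variant = c("io", "uca"), length = 6591L,
                                seed = NULL, config = two_group_config()) {
  variant <- match.arg(variant)
  blabs <- sprintf("b%d", 1:4)
  elabs <- sprintf("e%d", 1:4)
  with_seed(seed, {
    if (variant == "io") {
      pb <- sample_frequencies()
      pe <- if (isFALSE(config$shared_frequencies)) sample_frequencies() else pb
      mb <- substitution_model("LG+I+G+F", frequencies = pb,
                               alpha = config$alpha, p_inv = config$p_inv)
      me <- substitution_model("LG+I+G+F", frequencies = pe,
                               alpha = config$alpha, p_inv = config$p_inv)
      rb <- simulate_on_tree(.quartet_tree(blabs, config$b$terminal,
                                           config$b$internal),
                             mb, length, indels = config$indels)
      re <- simulate_on_tree(.quartet_tree(elabs, config$e$terminal,
                                           config$e$internal),
                             me, length, indels = config$indels)
      la <- nchar(rb$true_alignment[[1]])
      le <- nchar(re$true_alignment[[1]])
      w <- max(la, le)
      pad <- function(s, width)
        stats::setNames(paste0(s, strrep("-", width - nchar(s))), names(s))
      aln <- c(pad(rb$true_alignment, w), pad(re$true_alignment, w))
      structure(list(true_alignment = aln, sequences = strip_gaps(aln),
                     tree = list(B = rb$tree, E = re$tree),
                     model = list(B = mb, E = me), seed = seed,
                     partition = list(B = blabs, E = elabs)),
                class = "sim_result")
    } else {
      m <- substitution_model("LG+I+G+F", frequencies = sample_frequencies(),
                              alpha = config$alpha, p_inv = config$p_inv)
      j <- config$joining_branch
      txt <- sprintf(
        "(((%s:%g,%s:%g):%g,(%s:%g,%s:%g):%g):%g,((%s:%g,%s:%g):%g,(%s:%g,%s:%g):%g):%g);",
        blabs[1], config$b$terminal, blabs[2], config$b$terminal, config$b$internal / 2,
        blabs[3], config$b$terminal, blabs[4], config$b$terminal, config$b$internal / 2,
        j / 2,
        elabs[1], config$e$terminal, elabs[2], config$e$terminal, config$e$internal / 2,
        elabs[3], config$e$terminal, elabs[4], config$e$terminal, config$e$internal / 2,
        j / 2)
      res <- simulate_on_tree(read_newick(txt), m, length, indels = config$indels)
      res$partition <- list(B = blabs, E = elabs)
      res$seed <- seed
      res
    }
  })
}
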