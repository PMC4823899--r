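# Scripted, seeded experiments: the saturated-star model-selection sweep,
# the conservation-ordered segment sweep, the permutation-test calibration,
# and the separate-alignments comparison.  Each returns a report object
# with the full config echo, per-replicate rows and summary aggregates.

.experiment_report <- function(name, config, rows, summary) {
  structure(list(name = name, config = config, rows = rows,
                 summary = summary,
                 version = as.character(utils::packageVersion("ucatest"))),
            class = "uca_experiment")
}

#' @export
print.uca_experiment <- function(x, ...) {
  cat("Experiment:", x$name, "\n")
  cfg <- x$config[!vapply(x$config, is.list, TRUE)]
  cat("  config:",
      paste(names(cfg),
            vapply(cfg, function(v) paste(format(v), collapse = "/"), ""),
            sep = "=", collapse = ", "), "\n")
  cat("  rows:", nrow(x$rows), "\n  summary:\n")
  for (nm in names(x$summary))
    cat(sprintf("    %s = %s\n", nm, format(x$summary[[nm]])))
  invisible(x)
}

#' Saturated-star model-selection sweep
#'
#' Replicates of independently originated sequences on a saturated star
#' tree (two collapsed quartets by default), each run through the ancestry
#' model-selection test with the quartets as the putative origin groups and
#' no realignment.  Summaries report the fraction of replicates whose
#' delta AIC favours common ancestry (> 0) and strongly so (> 10) -- on
#' these data any such positive call is wrong by construction.
#'
#' @param n_reps number of replicates.
#' @param n_sequences,length,branch_length forwarded to
#'   [simulate_star_io()].
#' @param models model names offered to selection.
#' @param seed base seed; replicate r uses `seed + r`.
#' @return `"uca_experiment"` report.
#' @export
exp_saturated_star <- function(n_reps = 100, n_sequences = 8L, length = 1000L,
                               branch_length = 2500,
                               models = default_model_set(), seed = 1L) {
  stopifnot(n_reps >= 1)
  rows <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
    sim <- simulate_star_io(n_sequences, length, branch_length, seed = seed + r)
    tst <- uca_test(sim$true_alignment, sim$partition, models)
    data.frame(rep = r, delta_aic = tst$delta_aic, delta_bic = tst$delta_bic,
               uca_model = paste(tst$uca$model, collapse = "/"),
               io_model = paste(tst$io$model, collapse = "/"),
               classification = tst$classification,
               stringsAsFactors = FALSE)
  }))
  .experiment_report(
    "saturated-star model selection",
    list(n_reps = n_reps, n_sequences = n_sequences, length = length,
         branch_length = branch_length, models = models, seed = seed),
    rows,
    list(fraction_delta_aic_positive = mean(rows$delta_aic > 0),
         fraction_delta_aic_above_10 = mean(rows$delta_aic > 10),
         median_delta_aic = stats::median(rows$delta_aic)))
}

# per-column identity: matching pairs / comparable pairs among non-gaps
.column_identity <- function(m) {
  apply(m, 2, function(x) {
    x <- x[x != "-"]
    n <- length(x)
    if (n < 2) return(0)
    tab <- tabulate(factor(x, levels = .aa), nbins = 20)
    sum(tab * (tab - 1) / 2) / (n * (n - 1) / 2)
  })
}

#' Conservation-ordered segment sweep
#'
#' Simulates a long two-group data set, orders the true-alignment columns
#' by decreasing average identity (ties by original index), tiles them into
#' non-overlapping segments, and subjects every segment to the ancestry
#' test twice: on the true columns as-is, and after stripping gaps and
#' realigning the segment.  For independent-origins data the summaries
#' locate the identity levels above which the test always favours common
#' ancestry.
#'
#' @param total_columns root length of the simulated data sets.
#' @param segment segment width in columns.
#' @param variants which simulation conditions to run (`"io"`, `"uca"`).
#' @param realign also test each segment after realignment?
#' @param models model names offered to selection.
#' @param config a [two_group_config()].
#' @param seed integer seed.
#' @return `"uca_experiment"` report; rows carry per-segment pre-alignment
#'   identity and both delta AICs.
#' @export
exp_conserved_segments <- function(total_columns = 30000L, segment = 1000L,
                                   variants = c("io", "uca"), realign = TRUE,
                                   models = default_model_set(),
                                   config = two_group_config(), seed = 1L) {
  stopifnot(total_columns >= segment)
  rows <- do.call(rbind, lapply(variants, function(v) {
    sim <- simulate_two_groups(v, length = total_columns, seed = seed,
                               config = config)
    m <- seqs_to_matrix(sim$true_alignment)
    ord <- order(-.column_identity(m), seq_len(ncol(m)))
    m <- m[, ord, drop = FALSE]
    n_seg <- floor(ncol(m) / segment)
    do.call(rbind, lapply(seq_len(n_seg), function(s) {
      cols <- ((s - 1) * segment + 1):(s * segment)
      seg <- matrix_to_seqs(m[, cols, drop = FALSE])
      idn <- average_identity(seg)
      t1 <- uca_test(seg, sim$partition, models)
      out <- data.frame(variant = v, segment = s, identity = idn,
                        delta_aic = t1$delta_aic,
                        delta_aic_realigned = NA_real_,
                        stringsAsFactors = FALSE)
      if (realign) {
        un <- strip_gaps(seg)
        un <- un[nchar(un) > 0]
        if (length(un) >= 2 && length(unique(group_of(sim$partition,
                                                      names(un)))) > 1) {
          part <- lapply(sim$partition, intersect, names(un))
          part <- part[vapply(part, function(g) length(g) >= 2, TRUE)]
          if (length(part) >= 2) {
            t2 <- uca_test(progressive_align(un), part, models)
            out$delta_aic_realigned <- t2$delta_aic
          }
        }
      }
      out
    }))
  }))
  io <- rows[rows$variant == "io", , drop = FALSE]
  thr <- function(identity, delta) {
    bad <- delta <= 0
    if (!any(bad)) 0 else max(identity[bad])
  }
  summary <- list()
  if (nrow(io)) {
    ok <- !is.na(io$delta_aic_realigned)
    summary <- list(
      io_identity_threshold_unaligned = thr(io$identity, io$delta_aic),
      io_min_identity_positive = if (any(io$delta_aic > 0))
        min(io$identity[io$delta_aic > 0]) else NA_real_,
      io_identity_threshold_realigned = if (any(ok))
        thr(io$identity[ok], io$delta_aic_realigned[ok]) else NA_real_,
      io_fraction_positive = mean(io$delta_aic > 0))
  }
  if ("uca" %in% rows$variant)
    summary$uca_fraction_positive <-
      mean(rows$delta_aic[rows$variant == "uca"] > 0)
  .experiment_report(
    "conservation-ordered segments",
    list(total_columns = total_columns, segment = segment,
         variants = variants, realign = realign, models = models,
         seed = seed, config = config),
    rows, summary)
}

#' Permutation-test calibration sweep
#'
#' Simulates replicate data sets under both the independent-origins and the
#' common-ancestry variant of the two-group scenario and runs the
#' column-permutation test with both summary statistics on each, sharing
#' the realignment work between the statistics.  Under independent origins
#' the p-values should be uniform; under common ancestry they should
#' concentrate near zero.
#'
#' @param n_reps replicates per condition.
#' @param B null replicates per test.
#' @param length root sequence length.
#' @param config a [two_group_config()].
#' @param tree_search see [null_distribution()].
#' @param refine_alignments forward the aligner's guide-tree refinement
#'   pass (off by default here: the guide trees of these scaled data sets
#'   are unambiguous, and the sweep performs thousands of realignments).
#' @param seed base seed.
#' @return `"uca_experiment"` report; rows carry condition, statistic,
#'   observed value and p-value.
#' @export
exp_permutation <- function(n_reps = 50, B = 50, length = 500L,
                            config = two_group_config(),
                            tree_search = c("nj", "nni"),
                            refine_alignments = FALSE, seed = 1L) {
  tree_search <- match.arg(tree_search)
  align <- function(x) progressive_align(x, refine = refine_alignments)
  both <- function(aligned, partition) {
    c(tree_length = .perm_statistic(aligned, partition, "tree_length",
                                    tree_search),
      identity_diff = .perm_statistic(aligned, partition, "identity_diff",
                                      tree_search))
  }
  rows <- do.call(rbind, lapply(c("io", "uca"), function(v) {
    do.call(rbind, lapply(seq_len(n_reps), function(r) {
      base_seed <- seed + 1000L * (r + n_reps * (v == "uca"))
      sim <- simulate_two_groups(v, length = length, seed = base_seed,
                                 config = config)
      aligned <- align(sim$sequences)
      obs <- both(aligned, sim$partition)
      nulls <- vapply(seq_len(B), function(b) {
        shuf <- shuffle_group_columns(aligned, sim$partition[[1]],
                                      seed = base_seed + b)
        both(align(shuf), sim$partition)
      }, numeric(2))
      data.frame(condition = v, rep = r,
                 statistic = c("tree_length", "identity_diff"),
                 observed = obs,
                 p_value = c(permutation_pvalue(obs[1], nulls[1, ]),
                             permutation_pvalue(obs[2], nulls[2, ])),
                 stringsAsFactors = FALSE)
    }))
  }))
  sm <- list()
  for (st in c("tree_length", "identity_diff")) {
    io_p <- rows$p_value[rows$condition == "io" & rows$statistic == st]
    uca_p <- rows$p_value[rows$condition == "uca" & rows$statistic == st]
    io_o <- rows$observed[rows$condition == "io" & rows$statistic == st]
    uca_o <- rows$observed[rows$condition == "uca" & rows$statistic == st]
    sm[[paste0(st, "_ks_uniform_p_io")]] <-
      suppressWarnings(stats::ks.test(io_p, "punif")$p.value)
    sm[[paste0(st, "_ranksum_p_observed")]] <-
      suppressWarnings(stats::wilcox.test(io_o, uca_o)$p.value)
    sm[[paste0(st, "_power_uca_at_0.05")]] <- mean(uca_p <= 0.05)
    sm[[paste0(st, "_median_p_uca")]] <- stats::median(uca_p)
    sm[[paste0(st, "_median_p_io")]] <- stats::median(io_p)
  }
  .experiment_report(
    "permutation-test calibration",
    list(n_reps = n_reps, B = B, length = length, seed = seed,
         tree_search = tree_search, refine_alignments = refine_alignments,
         config = config),
    rows, sm)
}

#' Separate-alignments comparison sweep
#'
#' Replicates of the independent-origins two-group scenario with indels;
#' each group is aligned separately and the pooled set jointly, and the
#' scaled information-criterion differences plus the joint/separate
#' alignment-length ratio are recorded.
#'
#' @param n_reps number of replicates.
#' @param length root sequence length (default 6591 sites).
#' @param models model names offered to selection.
#' @param config a [two_group_config()] (indels enabled by default).
#' @param seed base seed.
#' @return `"uca_experiment"` report.
#' @export
exp_separate_alignments <- function(n_reps = 10, length = 6591L,
                                    models = default_model_set(),
                                    config = two_group_config(), seed = 1L) {
  rows <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
    sim <- simulate_two_groups("io", length = length, seed = seed + r,
                               config = config)
    groups <- lapply(sim$partition, function(ids) sim$sequences[ids])
    res <- uca_test_separate(groups, models)
    data.frame(rep = r,
               delta_aic_per_site = res$delta_aic_per_site,
               delta_bic_per_site = res$delta_bic_per_site,
               joint_length = res$joint_length,
               mean_separate_length = mean(res$group_lengths),
               length_ratio = res$length_ratio,
               stringsAsFactors = FALSE)
  }))
  .experiment_report(
    "separate-alignments comparison",
    list(n_reps = n_reps, length = length, models = models, seed = seed,
         config = config),
    rows,
    list(mean_length_ratio = mean(rows$length_ratio),
         mean_excess_percent = 100 * (mean(rows$length_ratio) - 1),
         fraction_delta_aic_positive = mean(rows$delta_aic_per_site > 0),
         mean_delta_aic_per_site = mean(rows$delta_aic_per_site)))
}

#' Write small seeded fixture data sets
#'
#' Deterministic small instances of every simulation scenario (FASTA for
#' the true alignment and the unaligned sequences, Newick trees, and a
#' plain-text metadata file), byte-identical on rerun with the same seed.
#'
#' @param out_dir writable output directory (created if needed).
#' @param seed integer seed.
#' @return invisibly, the written file paths.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  put <- function(sim, prefix) {
    p1 <- file.path(out_dir, paste0(prefix, ".true.fasta"))
    p2 <- file.path(out_dir, paste0(prefix, ".seqs.fasta"))
    write_fasta(sim$true_alignment, p1)
    write_fasta(sim$sequences, p2)
    files <- c(p1, p2)
    meta <- c(paste0("seed: ", seed))
    if (!is.null(sim$tree)) {
      trees <- if (inherits(sim$tree, "phylo")) list(tree = sim$tree) else sim$tree
      for (nm in names(trees))
        meta <- c(meta, paste0("tree_", nm, ": ", write_newick(trees[[nm]])))
    }
    if (!is.null(sim$model)) {
      mods <- if (inherits(sim$model, "substitution_model"))
        list(model = sim$model) else sim$model
      for (nm in names(mods))
        meta <- c(meta,
                  paste0("model_", nm, ": ", mods[[nm]]$name),
                  paste0("frequencies_", nm, ": ",
                         paste(signif(mods[[nm]]$frequencies, 8), collapse = " ")))
    }
    if (!is.null(sim$partition))
      for (nm in names(sim$partition))
        meta <- c(meta, paste0("group_", nm, ": ",
                               paste(sim$partition[[nm]], collapse = " ")))
    p3 <- file.path(out_dir, paste0(prefix, ".meta.txt"))
    writeLines(meta, p3)
    written <<- c(written, files, p3)
  }
  put(simulate_star_io(8, 200, seed = seed), "star-io-8x200")
  put(simulate_profile(8, 200, seed = seed, frequency_source = "per-site"),
      "profile-8x200")
  put(simulate_two_groups("io", length = 500, seed = seed), "two-groups-io-8x500")
  put(simulate_two_groups("uca", length = 500, seed = seed), "two-groups-uca-8x500")
  invisible(written)
}
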