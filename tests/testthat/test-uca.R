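test_that("information criteria are exact arithmetic", {
  expect_identical(aic(-100, 10), 220)
  expect_identical(bic(-100, 10, 1000), 10 * log(1000) + 200)
  expect_equal(bic(-7, 3, exp(1)), 3 + 14, tolerance = 1e-12)
  expect_error(bic(-1, 1, 0))
})

test_that("hypothesis fits satisfy their structural identities", {
  sim <- simulate_star_io(8, 150, 2500, seed = 71)
  aln <- sim$true_alignment
  models <- c("Poisson", "Poisson+F")

  io <- fit_hypothesis(aln, sim$partition, models)
  expect_equal(io$logLik, sum(vapply(io$groups, `[[`, 0, "logLik")))
  expect_identical(io$k, sum(vapply(io$groups, `[[`, 0L, "k")))
  expect_equal(io$AIC, sum(vapply(io$groups, `[[`, 0, "AIC")))
  expect_identical(io$n_sites, 150L)

  # nested pair sanity: the larger model cannot lose likelihood
  uca <- fit_hypothesis(aln, NULL, models)
  tab <- uca$groups[[1]]$table
  expect_gte(tab$logLik[tab$model == "Poisson+F"],
             tab$logLik[tab$model == "Poisson"] - 1e-3)

  expect_error(fit_hypothesis(aln, list(a = names(aln)[1],
                                        b = names(aln)[-1]), models),
               "at least 2")
})

test_that("the degenerate single-group partition yields a zero delta", {
  sim <- simulate_star_io(4, 80, 2500, seed = 73)
  res <- uca_test(sim$true_alignment, list(all = names(sim$true_alignment)),
                  models = c("Poisson", "Poisson+F"))
  expect_identical(res$delta_aic, 0)
  expect_identical(res$delta_bic, 0)
  expect_identical(res$classification, "favours-IO")
})

test_that("delta AIC is invariant to group relabelling and sequence order", {
  sim <- simulate_star_io(8, 120, 2500, seed = 79)
  aln <- sim$true_alignment
  models <- c("Poisson+F", "LG")
  r1 <- uca_test(aln, sim$partition, models)
  r2 <- uca_test(aln, rev(sim$partition), models)
  perm <- c(5, 1, 7, 3, 2, 8, 6, 4)
  r3 <- uca_test(aln[perm], sim$partition, models)
  expect_equal(r2$delta_aic, r1$delta_aic, tolerance = 1e-4)
  expect_equal(r3$delta_aic, r1$delta_aic, tolerance = 1e-4)
})

test_that("structured IO data drive group fits apart from the single-tree fit", {
  # identical twins within groups, saturation between: IO branch lengths
  # collapse, the single tree must carry a saturated branch
  pi <- sample_frequencies(seed = 83)
  m <- substitution_model("Poisson+F", frequencies = pi)
  sat <- simulate_on_tree(read_newick("(x:2500,y:2500);"), m, 400, seed = 83)
  aln <- c(a1 = sat$sequences[["x"]], a2 = sat$sequences[["x"]],
           b1 = sat$sequences[["y"]], b2 = sat$sequences[["y"]])
  part <- list(A = c("a1", "a2"), B = c("b1", "b2"))
  res <- uca_test(aln, part, models = c("Poisson+F"))
  for (g in res$io$groups)
    expect_lt(min(g$best$tree$edge.length), 1e-6)
  expect_true(res$uca$saturated)
  expect_false(any(vapply(res$io$groups, `[[`, TRUE, "saturated")))
})

test_that("the test favours UCA on genuinely common-ancestry data", {
  sim <- simulate_two_groups("uca", length = 400, seed = 89,
                             config = two_group_config(indels = NULL))
  res <- uca_test(sim$true_alignment, sim$partition)
  expect_gt(res$delta_aic, 0)
  expect_identical(res$classification, "strong-UCA")
})

test_that("forcing homogeneity shares one model and pooled frequencies across groups", {
  sim <- simulate_star_io(8, 120, 2500, seed = 91)
  res <- uca_test(sim$true_alignment, sim$partition,
                  models = c("Poisson+F", "LG"), force_homogeneous = TRUE)
  io_models <- res$io$model
  expect_identical(length(unique(io_models)), 1L)
  # homogeneity can only reduce the IO hypothesis' advantage
  free <- uca_test(sim$true_alignment, sim$partition,
                   models = c("Poisson+F", "LG"))
  expect_gte(res$delta_aic, free$delta_aic - 1e-6)
})

test_that("separate-alignment comparison reports scaled criteria and flags", {
  sim <- simulate_two_groups("io", length = 250, seed = 97)
  groups <- lapply(sim$partition, function(ids) sim$sequences[ids])
  res <- uca_test_separate(groups, models = c("Poisson+F", "LG+G"))
  expect_false(res$comparable)
  expect_gte(res$length_ratio, 1)
  expect_identical(res$joint_length, res$joint_fit$n_sites)
  # sign convention: delta recomputable from the parts
  expect_equal(res$delta_aic_per_site,
               (sum(vapply(res$group_fits, `[[`, 0, "AIC")) -
                  res$joint_fit$AIC) / res$joint_length,
               tolerance = 1e-12)
})
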