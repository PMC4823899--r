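test_that("sampled frequency vectors are valid and reproducible", {
  f1 <- sample_frequencies(seed = 10)
  f2 <- sample_frequencies(seed = 10)
  expect_identical(f1, f2)
  expect_true(all(f1 > 0))
  expect_equal(sum(f1), 1, tolerance = 1e-12)
  # symmetry of the normalized-uniform construction: marginal means ~ 1/20
  draws <- vapply(1:400, function(s) sample_frequencies(seed = 10000 + s), numeric(20))
  se <- apply(draws, 1, stats::sd) / sqrt(ncol(draws))
  expect_true(all(abs(rowMeans(draws) - 0.05) < 3 * se + 1e-3))
})

test_that("simulation on a tree respects degenerate and stationary limits", {
  m <- substitution_model("Poisson+F", frequencies = sample_frequencies(seed = 2))
  star0 <- read_newick("(a:0,b:0,c:0,d:0);")
  sim0 <- simulate_on_tree(star0, m, 50, seed = 1)
  expect_identical(length(unique(sim0$sequences)), 1L)

  # saturated pair: same-state frequency ~ sum(pi^2)
  pair <- read_newick("(a:2500,b:2500);")
  simS <- simulate_on_tree(pair, m, 10000, seed = 5)
  obs <- pairwise_identity(simS$sequences[[1]], simS$sequences[[2]])
  expval <- sum(m$frequencies^2)
  se <- sqrt(expval * (1 - expval) / 10000)
  expect_lt(abs(obs - expval), 3.5 * se)

  # short pair: identity follows the two-branch transition composition
  t <- 0.05
  simT <- simulate_on_tree(read_newick(sprintf("(a:%g,b:%g);", t, t)), m,
                           20000, seed = 6)
  q <- build_rate_matrix(m)
  p2t <- transition_matrix(q, 2 * t)
  expval <- sum(m$frequencies * diag(p2t))
  obs <- pairwise_identity(simT$sequences[[1]], simT$sequences[[2]])
  expect_lt(abs(obs - expval), 3.5 * sqrt(expval * (1 - expval) / 20000))
})

test_that("stationary simulations recover the equilibrium frequencies", {
  m <- substitution_model("LG")
  sim <- simulate_on_tree(read_newick("(a:1,b:1);"), m, 50000, seed = 3)
  counts <- table(factor(strsplit(paste(sim$sequences, collapse = ""),
                                  NULL)[[1]], levels = aa20))
  n <- sum(counts)
  for (a in aa20) {
    pa <- m$frequencies[a]
    se <- sqrt(pa * (1 - pa) / n)
    expect_lt(abs(counts[[a]] / n - pa), 4 * se + 1e-4)
  }
})

test_that("simulation is seed-deterministic and gap-strip consistent", {
  cfg <- two_group_config()
  s1 <- simulate_two_groups("io", length = 300, seed = 9, config = cfg)
  s2 <- simulate_two_groups("io", length = 300, seed = 9, config = cfg)
  expect_identical(s1$true_alignment, s2$true_alignment)
  expect_identical(strip_gaps(s1$true_alignment), s1$sequences)

  s3 <- simulate_two_groups("uca", length = 300, seed = 9)
  expect_identical(strip_gaps(s3$true_alignment), s3$sequences)
})

test_that("the saturated star scenario produces independent fixed-length groups", {
  sim <- simulate_star_io(8, 1000, 2500, seed = 4)
  expect_length(sim$sequences, 8)
  expect_true(all(nchar(sim$sequences) == 1000))
  expect_false(any(grepl("-", sim$true_alignment, fixed = TRUE)))
  expect_named(sim$partition, c("g1", "g2"))

  sim0 <- simulate_star_io(8, 200, 0, seed = 4)
  expect_identical(length(unique(sim0$sequences)), 1L)
})

test_that("profile-model simulation matches the saturated star distribution", {
  # shared mode and the saturated star are both iid-from-pi samplers;
  # compare their two-sequence joint pattern counts by chi-square
  n <- 20000
  p1 <- simulate_profile(2, n, seed = 21, frequency_source = "shared")
  p2 <- simulate_star_io(2, n, 2500, seed = 21)
  pat <- function(sim) {
    m <- do.call(rbind, strsplit(sim$sequences, NULL))
    table(factor(paste0(m[1, ], m[2, ]),
                 levels = as.vector(outer(aa20, aa20, paste0))))
  }
  tab <- rbind(pat(p1), pat(p2))
  keep <- colSums(tab) >= 10
  chi <- suppressWarnings(stats::chisq.test(tab[, keep]))
  expect_gt(chi$p.value, 0.01)

  expect_false(any(grepl("-", simulate_profile(4, 100, seed = 1,
                                               "per-site")$sequences)))
})

test_that("indel-free group scenarios keep exact root length", {
  cfg <- two_group_config(indels = NULL)
  sim <- simulate_two_groups("io", length = 400, seed = 2, config = cfg)
  expect_true(all(nchar(sim$sequences) == 400))
  expect_identical(nchar(sim$true_alignment[[1]]), 400L)
})

test_that("indels inflate the true alignment but keep homology bookkeeping", {
  cfg <- two_group_config(indels = indel_model(0.05, 0.05))
  sim <- simulate_two_groups("io", length = 400, seed = 12, config = cfg)
  expect_gte(nchar(sim$true_alignment[[1]]), max(nchar(sim$sequences)))
  expect_identical(strip_gaps(sim$true_alignment), sim$sequences)
  # no all-gap columns in the truth
  m <- do.call(rbind, strsplit(sim$true_alignment, NULL))
  expect_true(all(colSums(m != "-") > 0))
})
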