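test_that("pruning equals exhaustive ancestral enumeration", {
  # 3-leaf star, LG plain
  m3 <- substitution_model("LG")
  star <- read_newick("(a:0.2,b:0.45,c:0.08);")
  sim3 <- simulate_on_tree(star, m3, 40, seed = 17)
  expect_equal(log_likelihood(sim3$true_alignment, star, m3),
               enum_loglik_star3(sim3$true_alignment,
                                 c(0.2, 0.45, 0.08), m3),
               tolerance = 1e-8)

  # 4-taxon tree with gamma rates and a +F model, gaps as missing data
  pi <- sample_frequencies(seed = 18)
  m4 <- substitution_model("LG+G+F", frequencies = pi, alpha = 0.7)
  tr <- read_newick("((a:0.21,b:0.37):0.11,c:0.44,d:0.09);")
  sim4 <- simulate_on_tree(tr, m4, 40, seed = 18)
  aln <- sim4$true_alignment
  substr(aln[["a"]], 3, 5) <- "---"          # inject gaps
  expect_equal(log_likelihood(aln, tr, m4),
               enum_loglik_quartet(aln, 0.21, 0.37, 0.11, 0.44, 0.09, m4),
               tolerance = 1e-8)

  # invariant-sites category included
  m5 <- substitution_model("LG+I+G", alpha = 1.2, p_inv = 0.2)
  sim5 <- simulate_on_tree(tr, m5, 30, seed = 19)
  expect_equal(log_likelihood(sim5$true_alignment, tr, m5),
               enum_loglik_quartet(sim5$true_alignment,
                                   0.21, 0.37, 0.11, 0.44, 0.09, m5),
               tolerance = 1e-8)
})

test_that("simple likelihood values match hand calculation", {
  tr <- read_newick("(a:0,b:0);")
  m <- substitution_model("Poisson")
  expect_equal(log_likelihood(c(a = "A", b = "A"), tr, m), log(1 / 20),
               tolerance = 1e-12)
})

test_that("saturated branches drive the likelihood to the independence limit", {
  pi <- sample_frequencies(seed = 23)
  m <- substitution_model("Poisson+F", frequencies = pi)
  tr <- read_newick("(a:2500,b:2500,c:2500,d:2500);")
  sim <- simulate_on_tree(tr, m, 60, seed = 23)
  indep <- sum(vapply(sim$true_alignment, function(s)
    sum(log(pi[match(strsplit(s, NULL)[[1]], aa20)])), 0))
  expect_equal(log_likelihood(sim$true_alignment, tr, m), indep,
               tolerance = 1e-6)
})

test_that("likelihood is invariant to rerooting, leaf order and column order", {
  m <- substitution_model("LG+G", alpha = 1.1)
  tr <- read_newick("((a:0.2,b:0.3):0.1,(c:0.25,d:0.15):0.05);")
  sim <- simulate_on_tree(tr, m, 80, seed = 29)
  aln <- sim$true_alignment
  base <- log_likelihood(aln, tr, m)
  expect_equal(log_likelihood(aln, ape::root(tr, "c", resolve.root = TRUE), m),
               base, tolerance = 1e-6)
  expect_equal(log_likelihood(aln[c(3, 1, 4, 2)], tr, m), base,
               tolerance = 1e-10)
  perm <- sample(nchar(aln[[1]]))
  shuffled <- vapply(aln, function(s)
    paste(strsplit(s, NULL)[[1]][perm], collapse = ""), "")
  expect_equal(log_likelihood(shuffled, tr, m), base, tolerance = 1e-10)
  expect_error(log_likelihood(c(x = "AA", y = "AA"), tr, m), "match")
})

test_that("branch-length optimization recovers simulated lengths", {
  m <- substitution_model("Poisson+F", frequencies = sample_frequencies(seed = 37))
  for (t in c(0.1, 0.5, 1.0)) {
    sim <- simulate_on_tree(read_newick(sprintf("(a:%g,b:%g);", t / 2, t / 2)),
                            m, 10000, seed = 37)
    fit <- optimize_branch_lengths(sim$true_alignment,
                                   read_newick("(a:0.1,b:0.1);"), m)
    expect_lt(abs(sum(fit$edge.length) - t) / t, 0.1)
  }

  ident <- c(a = strrep("ARNDC", 40), b = strrep("ARNDC", 40))
  fit0 <- optimize_branch_lengths(ident, read_newick("(a:0.5,b:0.5);"), m)
  expect_lt(sum(fit0$edge.length), 1e-4)
})

test_that("saturated data push fitted branch lengths to the bound", {
  sim <- simulate_star_io(2, 2000, 2500, seed = 41)
  fit <- fit_phylo(sim$true_alignment, read_newick("(s1:1,s2:1);"), "Poisson+F")
  expect_true(fit$saturated)
})

test_that("NJ recovers additive metrics and ML search improves likelihood", {
  # additive quartet metric from a known tree
  true <- read_newick("((a:0.1,b:0.2):0.05,(c:0.15,d:0.25):0.05);")
  dm <- ape::cophenetic.phylo(true)
  nj <- nj_tree(dm)
  expect_identical(as.numeric(ape::dist.topo(ape::unroot(nj), ape::unroot(true))), 0)

  m <- substitution_model("LG")
  sim <- simulate_on_tree(true, m, 500, seed = 43)
  fit <- ml_tree(sim$true_alignment, "LG")
  expect_identical(as.numeric(ape::dist.topo(ape::unroot(fit$tree), ape::unroot(true))), 0)
  # exhaustive quartet search returns the best of the three topologies
  alts <- phangorn::allTrees(4, rooted = FALSE,
                             tip.label = names(sim$true_alignment))
  lnls <- vapply(alts, function(tr) {
    tr$edge.length <- rep(0.1, nrow(tr$edge))
    fit_phylo(sim$true_alignment, tr, "LG")$logLik
  }, 0)
  expect_equal(fit$logLik, max(lnls), tolerance = 1e-2)
})

test_that("tree length is the plain branch-length sum", {
  expect_identical(tree_length(read_newick("(a:2500,b:2500,c:2500,d:2500);")),
                   10000)
  expect_identical(tree_length(read_newick("(a:0,b:0,c:0);")), 0)
  tr <- read_newick("((a:1,b:2):0.5,(c:3,d:4):0.25);")
  expect_equal(tree_length(ape::root(tr, "a", resolve.root = TRUE)),
               tree_length(tr))
})
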