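test_that("closed-form Poisson transition probabilities behave as derived", {
  pi <- sample_frequencies(seed = 7)
  unif <- rep(1 / 20, 20)

  expect_equal(poisson_transition("A", "A", 0, pi), 1, ignore_attr = TRUE)
  # infinite branch: the end state forgets the start state entirely
  expect_equal(poisson_transition("A", "W", Inf, pi), unname(pi["W"]),
               ignore_attr = TRUE)
  expect_equal(poisson_transition("C", "C", 1, unif),
               exp(-1) + (1 - exp(-1)) / 20, ignore_attr = TRUE)
  expect_error(poisson_transition("A", "A", -1, pi), "negative")

  # rows sum to one for a grid of t
  for (t in c(0, 0.3, 2, 50, Inf)) {
    p <- vapply(aa20, function(b) poisson_transition("R", b, t, pi), 0)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("two-sequence joint probabilities interpolate stationarity", {
  pi <- sample_frequencies(seed = 3)
  expect_equal(pair_joint_probability("A", "A", 0, pi), unname(pi["A"]),
               ignore_attr = TRUE)
  expect_equal(pair_joint_probability("A", "A", Inf, pi), unname(pi["A"]^2),
               ignore_attr = TRUE)
  expect_equal(pair_joint_probability("A", "R", Inf, pi),
               unname(pi["A"] * pi["R"]), ignore_attr = TRUE)
  for (t in c(0, 0.7, 3)) {
    tot <- sum(outer(aa20, aa20, function(a, b)
      pair_joint_probability(a, b, t, pi)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("rate matrices are valid generators with unit mean rate", {
  for (name in c("Poisson", "Poisson+F", "LG", "LG+I+G+F")) {
    m <- substitution_model(name, frequencies = if (grepl("F", name))
      sample_frequencies(seed = 11) else NULL)
    q <- build_rate_matrix(m)
    expect_equal(rowSums(q), rep(0, 20), tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(-sum(m$frequencies * diag(q)), 1, tolerance = 1e-12)
    # time reversibility: pi_a q_ab symmetric
    flux <- m$frequencies * q
    expect_equal(flux, t(flux), tolerance = 1e-12)
  }
})

test_that("the closed form equals the matrix exponential of the Poisson generator", {
  pi <- sample_frequencies(seed = 5)
  m <- substitution_model("Poisson+F", frequencies = pi)
  q <- build_rate_matrix(m, normalize = FALSE)   # jump-chain generator
  for (t in c(0.1, 0.5, 1, 2, 10)) {
    p <- transition_matrix(q, t)
    closed <- outer(1:20, 1:20, function(a, b)
      poisson_transition(a, b, t, pi))
    expect_equal(unname(p), unname(closed), tolerance = 1e-10)
  }
})

test_that("transition matrices are stochastic, stationary and consistent", {
  m <- substitution_model("LG+G", alpha = 0.8)
  q <- build_rate_matrix(m)
  pi <- m$frequencies
  set.seed(1)
  for (t in c(0, 0.05, 1.3, 49)) {
    p <- transition_matrix(q, t)
    expect_equal(rowSums(p), rep(1, 20), tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(as.numeric(pi %*% p), unname(pi), tolerance = 1e-10)
  }
  expect_identical(unname(transition_matrix(q, 0)), diag(20))
  # computationally stationary at huge lengths
  p2500 <- transition_matrix(q, 2500, 1)
  expect_equal(unname(p2500), matrix(pi, 20, 20, byrow = TRUE),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unname(transition_matrix(q, 2e4, 1)),
               matrix(pi, 20, 20, byrow = TRUE), tolerance = 1e-12,
               ignore_attr = TRUE)
  # Chapman-Kolmogorov at random pairs
  for (i in 1:3) {
    t1 <- runif(1, 0, 2); t2 <- runif(1, 0, 2)
    expect_equal(transition_matrix(q, t1) %*% transition_matrix(q, t2),
                 transition_matrix(q, t1 + t2), tolerance = 1e-10)
  }
  expect_error(transition_matrix(q, -0.1), "negative")
})

test_that("discrete gamma categories have unit mean and sane limits", {
  expect_identical(discrete_gamma(2, 1), list(rates = 1, weights = 1))
  g <- discrete_gamma(1e6, 4)
  expect_true(all(abs(g$rates - 1) < 1e-2))
  for (alpha in c(0.2, 0.5, 1, 3)) {
    g <- discrete_gamma(alpha, 4)
    expect_equal(sum(g$rates * g$weights), 1, tolerance = 1e-12)
    expect_identical(g$rates, sort(g$rates))
  }
  expect_error(discrete_gamma(-1, 4))
})

test_that("invariant sites fold in as a zero-rate category", {
  m <- substitution_model("LG+I+G", alpha = 0.9, p_inv = 0.25)
  rc <- rate_categories(m)
  expect_length(rc$rates, 5)
  expect_identical(rc$rates[1], 0)
  expect_equal(rc$weights[1], 0.25)
  expect_equal(sum(rc$weights), 1, tolerance = 1e-12)
  expect_equal(sum(rc$rates * rc$weights), 1, tolerance = 1e-12)
})

test_that("free-parameter counts follow the +F/+I/+G conventions", {
  counts <- vapply(default_model_set(), parameter_count, 0L)
  expect_identical(unname(counts), c(0L, 19L, 0L, 1L, 2L, 21L))
})
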