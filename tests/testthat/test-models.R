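test_that("the model family enumerates sixteen members in four groups", {
  specs <- model_specs()
  expect_equal(nrow(specs), 16)
  expect_equal(length(unique(specs$name)), 16)
  expect_equal(as.vector(table(specs$group)), rep(4L, 4))
  expect_setequal(specs$name[specs$group == "II"],
                  c("Km", "KmG", "KAm", "KAmG"))
  expect_setequal(specs$name[specs$group == "IV"],
                  c("KmD", "KAmD", "KmDG", "KAmDG"))
  # ordering is deterministic: group, then name
  expect_identical(specs, model_specs())
  expect_false(model_spec("K")$free_A)
  expect_error(model_spec("KX"), "Unknown model")
  # fixed-parameter conventions
  prm <- generative_params(model_spec("K"), K = 0.05, G = 0.1)
  expect_equal(unname(prm[c("A", "m", "D")]), c(1, 0, 0))
})

test_that("initial gain estimate averages the leading window", {
  expect_equal(initial_gain_estimate(rep(0.1, 10)), 0.1)
  expect_equal(initial_gain_estimate(c(0, 0.5, -0.5, 0.2, -0.2, 9)), 0)
  expect_equal(initial_gain_estimate(c(0.3, 1, 1), window = 1), 0.3)
  expect_error(initial_gain_estimate(numeric(0)), "Empty")
  expect_error(initial_gain_estimate(c(1, 2), window = 5), "shorter")
})

test_that("the recursion contracts, drifts and tracks as the algebra says", {
  n <- 1:300
  # zero stimulus, A = 1: pure geometric contraction x(n) = (1-K)^(n-1)
  x <- simulate_state(rep(0, 300), K = 0.02, A = 1, G = 1)
  expect_equal(as.numeric(x), 0.98^(n - 1))
  # drift: fixed point m/K when A = 1
  x <- simulate_state(rep(0, 5000), K = 0.02, A = 1, m = -0.004, G = 0)
  expect_equal(x[5000], -0.2, tolerance = 1e-8)
})

test_that("simulation equals the explicit convolution solution when D = 0", {
  set.seed(42)
  s <- rnorm(200)
  for (prm in list(c(K = 0.02, A = 1, m = 0, G = 1),
                   c(K = 0.1, A = 0.97, m = -0.004, G = -0.3),
                   c(K = 0.3, A = 0.99, m = 0.01, G = 0))) {
    x <- simulate_state(s, K = prm[["K"]], A = prm[["A"]], m = prm[["m"]],
                        G = prm[["G"]])
    xc <- conv_solution(prm[["K"]], prm[["A"]], prm[["m"]], s, prm[["G"]])
    expect_equal(as.numeric(x), xc, tolerance = 1e-12)
  }
})

test_that("stability matches the companion-matrix eigenvalues", {
  set.seed(7)
  for (i in 1:200) {
    K <- runif(1, 0, 0.5); A <- runif(1, 0.9, 1.05); D <- runif(1, -0.4, 0.1)
    comp <- matrix(c(A - K, -D, 1, 0), 2, 2, byrow = TRUE)
    oracle <- max(Mod(eigen(comp, only.values = TRUE)$values)) < 1
    expect_identical(is_stable(K, A, D), oracle)
  }
  # simulate flags divergence for clearly unstable parameters, not raises
  x <- simulate_state(rep(0, 2000), K = 0.01, A = 1, D = -0.3, G = 0.01)
  expect_true(attr(x, "unstable"))
  expect_true(all(is.finite(x)))
  x <- simulate_state(rep(0, 2000), K = 0.15, A = 0.99, D = -0.13, G = 1)
  expect_false(attr(x, "unstable"))
})

test_that("the learner is linear in the stimulus when m = 0 and G = 0", {
  set.seed(11)
  s1 <- rnorm(150); s2 <- rnorm(150)
  sim <- function(s) simulate_state(s, K = 0.15, A = 0.99, D = -0.13, G = 0)
  expect_equal(as.numeric(sim(2 * s1 - 0.5 * s2)),
               as.numeric(2 * sim(s1) - 0.5 * sim(s2)),
               tolerance = 1e-12)
})

test_that("the two-learner decomposition is exact", {
  tr <- build_session(single_block_design(6))
  x <- simulate_state(tr$s, K = 0.15, A = 0.99, D = -0.13, G = 0.1)
  tl <- two_learner_view(tr, x, K = 0.15, D = -0.13)
  expect_equal(attr(tl, "kappa"), 0.02)
  expect_equal(attr(tl, "eta"), 0.28)
  expect_equal(tl$X_plus + tl$X_minus, tl$x)
  expect_equal(tl$S_plus + tl$S_minus, tl$s)
  # constant stimulus: the difference channel input vanishes (after the
  # start-up trial, which uses the s(0) = 0 convention)
  tlc <- two_learner_view(rep(0.8, 50), rep(0, 50), K = 0.1, D = -0.05)
  expect_true(all(tlc$S_minus[-1] == 0))
  expect_equal(tlc$S_plus[-1], rep(0.8, 49))
})
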