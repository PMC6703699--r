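make_segment <- function(f = 6, n_pre = 75, n_adapt = 384) {
  build_session(single_block_design(f, n_pre = n_pre, n_adapt = n_adapt))
}

test_that("the predictor is piecewise: sinusoid from adaptation onset only", {
  tr <- make_segment()
  # a = 0: pure drift model
  g <- phenom_predict(tr, a = 0, nu = 6, phi = 0, B = 0.3, lambda = 0.01,
                      B0 = -0.2)
  n <- seq_len(nrow(tr))
  expect_equal(g, 0.3 * exp(-0.01 * n) - 0.2)
  # B = B0 = 0: zeros before onset, lagged sinusoid after
  g <- phenom_predict(tr, a = 0.3, nu = 6, phi = 0.5, B = 0, lambda = 0,
                      B0 = 0)
  expect_true(all(g[1:75] == 0))
  om <- 2 * pi * 6 / 384
  expect_equal(g[76:459], 0.3 * sin(om * (1:384) - 0.5))
})

test_that("analytic phenomenology reproduces the post-transient simulation", {
  tr <- make_segment()
  K <- 0.05; A <- 1; m <- -0.004
  x <- simulate_state(tr$s, K = K, A = A, m = m, G = 0)
  pp <- predict_phenom_params(K, A, m, 0, f = 6)
  g_hat <- phenom_predict(tr, a = pp$a, nu = 6, phi = pp$total_lag,
                          B = 0, lambda = 0, B0 = pp$B0)
  post <- 275:459  # transient (~1/K trials) has decayed
  expect_lt(sqrt(mean((x[post] - g_hat[post])^2)), 1e-3)
})

test_that("noise-free phenomenological data is recovered near-exactly", {
  tr <- make_segment()
  truth <- c(a = 0.3, nu = 6, phi = 0.5, B = 0.2, lambda = 0.01, B0 = -0.2)
  tr$g <- phenom_predict(tr, 0.3, 6, 0.5, 0.2, 0.01, -0.2)
  fit <- fit_phenom(tr)
  expect_true(fit$converged)
  rel <- abs(fit$estimates[names(truth)] - truth) / abs(truth)
  expect_lt(max(rel), 1e-6)
})

test_that("the response frequency is reliably estimated across the session", {
  d <- freq_design()
  obs <- generate_observer(d, c(K = 0.025, A = 0.995, m = -0.004, G = 0),
                           sigma = 0.1, seed = 99)
  for (f in c(1, 3, 6, 12, 24)) {
    seg <- session_segment(obs, f)
    fit <- fit_phenom(seg)
    expect_lt(abs(fit$estimates[["nu"]] - f), 0.2)
  }
})

test_that("white noise about a constant gives no support to the sinusoid", {
  tr <- make_segment(n_pre = 25, n_adapt = 96)
  set.seed(123)
  tr$g <- -0.1 + rnorm(nrow(tr), 0, 0.1)
  fit <- fit_phenom(tr)
  expect_lt(abs(fit$estimates[["a"]]), 0.06)
  er <- evidence_report(tr)
  expect_lt(er$db_full_vs_noise, 3)
  expect_lt(er$db_full_vs_drift, 3)
})

test_that("evidence is zero on identity, antisymmetric, and additive", {
  tr <- make_segment(n_pre = 25, n_adapt = 96)
  set.seed(5)
  tr$g <- phenom_predict(tr, 0.3, 3, 0.5, 0.2, 0.02, -0.2) +
    rnorm(nrow(tr), 0, 0.1)
  expect_identical(evidence_db(tr, "drift", "drift"), 0)
  expect_equal(evidence_db(tr, "full", "noise"),
               -evidence_db(tr, "noise", "full"))
  er <- evidence_report(tr)
  expect_identical(er$db_full_vs_noise,
                   er$db_full_vs_drift + er$db_drift_vs_noise)
  expect_error(evidence_db(tr, "full", "saturated"), "nested")
})

test_that("posteriors concentrate with trial count", {
  om_design <- function(n_adapt, f) {
    build_session(single_block_design(f, n_pre = 10, n_adapt = n_adapt))
  }
  truth <- c(a = 0.3, phi = 0.5, B = 0.2, lambda = 0.02, B0 = -0.2)
  fit_sd <- function(n_adapt, f, seed) {
    tr <- om_design(n_adapt, f)
    set.seed(seed)
    tr$g <- phenom_predict(tr, 0.3, f, 0.5, 0.2, 0.02, -0.2) +
      rnorm(nrow(tr), 0, 0.1)
    fit <- fit_phenom(tr)
    stats::setNames(fit$params$sd, fit$params$term)
  }
  # same per-trial angular frequency, ten times the data
  sd_small <- fit_sd(190, 3, 21)
  sd_large <- fit_sd(1900, 30, 22)
  for (term in c("a", "phi", "B0")) {
    expect_lt(sd_large[[term]], sd_small[[term]])
  }
})

test_that("evidence is invariant under joint rescaling of data and priors", {
  tr <- make_segment(n_pre = 25, n_adapt = 96)
  set.seed(31)
  tr$g <- phenom_predict(tr, 0.3, 3, 0.5, 0.2, 0.02, -0.2) +
    rnorm(nrow(tr), 0, 0.1)
  er1 <- evidence_report(tr)
  tr2 <- tr
  tr2$g <- 2 * tr$g
  pr2 <- phenom_priors(a = c(0, 4), B = c(-4, 4), B0 = c(-4, 4))
  er2 <- evidence_report(tr2, priors = pr2)
  expect_equal(er1$db_full_vs_drift, er2$db_full_vs_drift, tolerance = 1e-6)
  expect_equal(er1$db_drift_vs_noise, er2$db_drift_vs_noise,
               tolerance = 1e-6)
})

test_that("population pooling weights by inverse variance", {
  expect_equal(weighted_population_estimate(c(1, 3), c(1, 1)), 2)
  expect_lt(abs(weighted_population_estimate(c(0, 10), c(1, 1e6))), 1e-9)
  expect_equal(weighted_population_estimate(0.7, 2), 0.7)
  expect_error(weighted_population_estimate(c(1, 2), c(1, 0)), "floor")
  expect_error(weighted_population_estimate(c(1, 2), 1), "length")
})

test_that("fit accessors return tidy shapes", {
  tr <- make_segment(n_pre = 25, n_adapt = 96)
  set.seed(8)
  tr$g <- phenom_predict(tr, 0.3, 3, 0.5, 0.2, 0.02, -0.2) +
    rnorm(nrow(tr), 0, 0.1)
  fit <- fit_phenom(tr)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$term, c("a", "nu", "phi", "B", "lambda", "B0"))
  expect_true(all(td$sd >= 0))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_error(fit_phenom(dplyr::select(tr, -"g")), "`g`")
})
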