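test_that("observer generation is seeded, noise-layered and validated", {
  d <- single_block_design(6)
  prm <- c(K = 0.02, A = 0.99, m = -0.004, G = 0)
  # sigma = 0: observed gain equals the latent state
  obs0 <- generate_observer(d, prm, sigma = 0, seed = 1)
  expect_identical(obs0$g, obs0$x)
  # same seed, same series; different seed, different noise
  a <- generate_observer(d, prm, sigma = 0.1, seed = 2)
  b <- generate_observer(d, prm, sigma = 0.1, seed = 2)
  c3 <- generate_observer(d, prm, sigma = 0.1, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a$g, c3$g))
  expect_identical(a$x, c3$x)
  # unstable truths are rejected at generation
  expect_error(generate_observer(d, c(K = 0.01, A = 1, D = -0.3, G = 0)),
               "[Uu]nstable")
})

test_that("observation noise has the configured variance", {
  d <- freq_design()  # 2370 trials
  obs <- generate_observer(d, c(K = 0.02, A = 0.99, m = -0.004, G = 0),
                           sigma = 0.1, seed = 42)
  v <- stats::var(obs$g - obs$x)
  # chi-square 95% band for the sample variance at n = 2370
  expect_gt(v, 0.009)
  expect_lt(v, 0.011)
})

test_that("cohort counting matches the two-design two-way bookkeeping", {
  freq_cohort <- generate_cohort(freq_design(), "KAm", n_participants = 13,
                                 seed = 1)
  runs_freq <- sum(vapply(freq_cohort$trials, function(tr) {
    length(unique(tr$block[tr$block_type == "adaptation"]))
  }, numeric(1)))
  expect_equal(runs_freq, 13 * 5)
  runs_orig <- 10 * 3  # 10 participants, one block per session, 3 sessions
  expect_equal(runs_freq + runs_orig, 95)
  # manifest structure
  expect_setequal(names(freq_cohort),
                  c("participant", "seed", "K", "A", "m", "D", "G",
                    "sigma", "trials"))
  # fixed-parameter conventions hold in the drawn truths
  expect_true(all(freq_cohort$D == 0))
  expect_true(all(freq_cohort$sigma == default_sigma("two-way")))
})

test_that("global cohorts draw smaller rates and more noise", {
  tw <- truth_ranges("KAm", "two-way")
  gl <- truth_ranges("KAm", "global")
  expect_lt(gl$K[2], tw$K[2])
  expect_lt(gl$K[1], tw$K[1])
  expect_gt(default_sigma("global"), default_sigma("two-way"))
  # double-error ranges are an order of magnitude up and stay stable
  iv <- truth_ranges("KAmDG", "two-way")
  expect_gt(iv$K[1], 3 * tw$K[2])
  expect_lt(iv$D[2], 0)
})

test_that("recovery experiments are reproducible and unbiased at low noise", {
  d <- single_block_design(6, n_pre = 25, n_adapt = 192)
  run <- function(sigma) {
    recovery_experiment(d, "KAmG",
                        truth = list(K = 0.02, A = 0.99, m = -0.004),
                        sigma = sigma, n_participants = 3,
                        n_replicates = 2, seed = 7, n_starts = 3)
  }
  r1 <- run(0.05)
  r2 <- run(0.05)
  expect_identical(r1$estimates, r2$estimates)
  # noise-free: bias vanishes
  r0 <- run(0)
  expect_lt(max(abs(r0$summary$bias)), 1e-6)
  # small noise: bias stays small
  r_small <- run(0.02)
  expect_lt(max(abs(r_small$summary$bias)), 0.01)
})

test_that("child seeds are stable under cohort extension", {
  expect_identical(child_seed(1, 1, 1), child_seed(1, 1, 1))
  s1 <- vapply(1:10, function(i) child_seed(99, i, 2), integer(1))
  expect_equal(length(unique(s1)), 10)
  expect_true(all(s1 >= 0 & s1 < 2^31))
  # adding participants does not reshuffle earlier ones
  s2 <- vapply(1:20, function(i) child_seed(99, i, 2), integer(1))
  expect_identical(s2[1:10], s1)
})

test_that("synthetic cohorts carry the phenomenological signature", {
  d <- single_block_design(6)
  obs <- generate_observer(d, c(K = 0.15, A = 0.99, m = -0.004, D = -0.13,
                                G = 0), sigma = 0, seed = 13)
  fit <- fit_phenom(obs)
  expect_lt(abs(fit$estimates[["nu"]] - 6), 0.2)
  expect_lt(fit$estimates[["B0"]], 0)  # drift toward hypometria
  pp <- predict_phenom_params(0.15, 0.99, -0.004, -0.13, f = 6)
  expect_equal(fit$estimates[["a"]], pp$a, tolerance = 0.02)
})
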