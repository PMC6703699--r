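# Truth state series whose five-trial initial-gain estimate equals the
# generating G, so fixed-G models can reproduce it exactly. The map
# G -> mean(x(G)[1:5]) is affine (the recursion is linear in G); its fixed
# point is solved from two simulations.
self_consistent_series <- function(trials, K, A, m, D = 0) {
  f5 <- function(G) {
    mean(simulate_state(trials$s, K = K, A = A, m = m, D = D, G = G)[1:5])
  }
  a <- f5(0)
  b <- f5(1) - a
  G_star <- a / (1 - b)
  simulate_state(trials$s, K = K, A = A, m = m, D = D, G = G_star)
}

test_that("noise-free series are recovered exactly by the truth model", {
  tr <- build_session(single_block_design(6))
  tr$g <- self_consistent_series(tr, K = 0.02, A = 0.99, m = -0.004)
  set.seed(1)
  fit <- fit_state_model(tr, "KAm", n_starts = 4)
  expect_true(fit$converged)
  expect_lt(abs(fit$params[["K"]] - 0.02), 1e-6)
  expect_lt(abs(fit$params[["A"]] - 0.99), 1e-6)
  expect_lt(abs(fit$params[["m"]] + 0.004), 1e-6)
  expect_lt(fit$rss, 1e-12)
  # free-G variant, now with arbitrary truth G
  tr$g <- simulate_state(tr$s, K = 0.15, A = 0.99, m = -0.004, D = -0.13,
                         G = 0.07)
  set.seed(2)
  fit <- fit_state_model(tr, "KAmDG", n_starts = 6)
  truth <- c(K = 0.15, A = 0.99, m = -0.004, D = -0.13, G = 0.07)
  expect_lt(max(abs(fit$params[names(truth)] - truth)), 1e-6)
})

test_that("nested models cannot beat their supersets on rss", {
  obs <- generate_observer(single_block_design(6),
                           c(K = 0.02, A = 0.99, m = -0.004, G = 0),
                           sigma = 0.1, seed = 3)
  set.seed(4)
  fit_k <- fit_state_model(obs, "K", n_starts = 4)
  set.seed(4)
  fit_kam <- fit_state_model(obs, "KAm", n_starts = 4)
  expect_gt(fit_k$rss, fit_kam$rss)
  # rss monotone along a nested chain
  set.seed(4)
  fit_kamdg <- fit_state_model(obs, "KAmDG", n_starts = 6)
  expect_gt(fit_kam$rss, fit_kamdg$rss - 1e-12)
})

test_that("confidence intervals behave like linearization intervals", {
  tr <- build_session(single_block_design(6))
  x <- self_consistent_series(tr, K = 0.02, A = 0.99, m = -0.004)
  # sigma = 0: interval widths collapse
  tr$g <- x
  set.seed(5)
  fit0 <- fit_state_model(tr, "KAm", n_starts = 2)
  expect_lt(max(fit0$params_tbl$conf.high - fit0$params_tbl$conf.low), 1e-5)
  # only free parameters carry intervals
  expect_setequal(fit0$params_tbl$term, c("K", "A", "m"))
  # doubling sigma roughly doubles the widths (same noise draw, rescaled)
  set.seed(6)
  eps <- rnorm(nrow(tr))
  width <- function(sigma) {
    tr$g <- x + sigma * eps
    set.seed(7)
    fit <- fit_state_model(tr, "KAm", n_starts = 4)
    fit$params_tbl$conf.high - fit$params_tbl$conf.low
  }
  ratio <- width(0.1) / width(0.05)
  expect_true(all(ratio > 1.5 & ratio < 2.6))
})

test_that("akaike weights follow the exp(-delta/2) rule", {
  expect_equal(akaike_weights(100), 1)
  expect_equal(akaike_weights(c(50, 50)), c(0.5, 0.5))
  w <- akaike_weights(c(100, 102))  # equal rss, one extra parameter
  expect_equal(w, c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  expect_equal(sum(akaike_weights(c(3, 9, 2, 14))), 1)
})

test_that("weight averaging preserves normalization", {
  w1 <- c(K = 1, KA = 0, Km = 0)
  w2 <- c(K = 0, KA = 1, Km = 0)
  avg <- average_weights(rbind(w1, w2))
  expect_equal(avg$weight, c(0.5, 0.5, 0))
  expect_equal(sum(avg$weight), 1)
  avg1 <- average_weights(list(w1, w1))
  expect_equal(avg1$weight, unname(w1))
  # tie-break: fewer free parameters, then name
  tie <- tibble::tibble(model = c("KAmDG", "K", "KA"),
                        weight = c(0.4, 0.4, 0.2))
  expect_equal(best_model(tie), "K")
})

test_that("fitting depends only on the (s, g) pairing", {
  obs <- generate_observer(single_block_design(3),
                           c(K = 0.03, A = 0.99, m = -0.004, G = 0),
                           sigma = 0.08, seed = 8)
  set.seed(9)
  fit_full <- fit_state_model(obs, "KAm", n_starts = 3)
  relabeled <- obs
  relabeled$block <- rev(relabeled$block)
  relabeled$block_type <- sample(relabeled$block_type)
  set.seed(9)
  fit_rel <- fit_state_model(relabeled, "KAm", n_starts = 3)
  expect_identical(fit_full$params, fit_rel$params)
})

test_that("family fits produce a normalized selection table", {
  obs <- generate_observer(single_block_design(6),
                           c(K = 0.15, A = 0.99, m = -0.004, D = -0.13,
                             G = 0),
                           sigma = 0.1, seed = 10)
  set.seed(11)
  fam <- fit_state_models(obs, n_starts = 4)
  expect_equal(nrow(fam), 16)
  expect_equal(sum(fam$weight), 1)
  gw <- group_weights(fam[, c("model", "weight")])
  expect_equal(sum(gw$weight), 1)
  expect_s3_class(autoplot(fam$fit[[which.max(fam$weight)]]), "ggplot")
})
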