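#' Prior ranges for the phenomenological parameters
#'
#' Uniform box priors used by [fit_phenom()] and the evidence computation.
#' Defaults: amplitude `a` in `[0, 2]` gain units, response frequency `nu`
#' in `[0.5, 30]` cpb, lag `phi` in `[-pi, pi]` radians, decay amplitude
#' `B` in `[-2, 2]`, decay timescale `lambda` in `[0, 0.5]` per trial,
#' asymptote `B0` in `[-2, 2]`.
#'
#' @param a,nu,phi,B,lambda,B0 Length-2 numeric ranges.
#' @return Named list of ranges.
#' @export
phenom_priors <- function(a = c(0, 2), nu = c(0.5, 30), phi = c(-pi, pi),
                          B = c(-2, 2), lambda = c(0, 0.5), B0 = c(-2, 2)) {
  pr <- list(a = a, nu = nu, phi = phi, B = B, lambda = lambda, B0 = B0)
  ok <- vapply(pr, function(r) length(r) == 2 && all(is.finite(r)) &&
                 r[1] < r[2], logical(1))
  if (!all(ok)) stop("Prior ranges must be finite length-2 intervals.",
                     call. = FALSE)
  pr
}

# Segment bookkeeping: one adaptation block (plus optional pre block).
# Returns the within-adaptation index (0 before onset), the fitted-trial
# index (1-based from the first fitted trial) and the adaptation length N.
.segment_info <- function(trials) {
  if (!all(c("block_type", "s") %in% names(trials))) {
    stop("`trials` must carry `block_type` and `s` columns ",
         "(see `build_session()`).", call. = FALSE)
  }
  adapt <- trials$block_type == "adaptation"
  if (!any(adapt)) stop("Segment contains no adaptation trials.",
                        call. = FALSE)
  blocks <- unique(trials$block[adapt])
  if (length(blocks) > 1) {
    stop("Fit one pre + adaptation segment at a time; ",
         "see `session_segment()`.", call. = FALSE)
  }
  n_ad <- integer(nrow(trials))
  n_ad[adapt] <- seq_len(sum(adapt))
  list(adapt = adapt, n_ad = n_ad, n_fit = seq_len(nrow(trials)),
       N = sum(adapt))
}

#' Predicted gain under the phenomenological model
#'
#' The descriptive model is a lagged sinusoid riding on an exponentially
#' decaying baseline:
#' `g(n) = a*sin(omega*n_ad - phi) + B*exp(-lambda*n) + B0`,
#' `omega = 2*pi*nu/N`. The sinusoid onsets at the first adaptation trial
#' (its argument counts trials from adaptation onset); the exponential and
#' the asymptote span the whole fitted segment (argument counted from the
#' first fitted trial), so pre-adaptation trials constrain the baseline.
#'
#' @param trials Trial tibble covering at most one adaptation block (plus
#'   its pre-adaptation block).
#' @param a,nu,phi,B,lambda,B0 Phenomenological parameters ([phenom_priors()]
#'   names).
#' @return Numeric vector of predicted gains, one per row of `trials`.
#' @examples
#' tr <- build_session(single_block_design(6))
#' g_hat <- phenom_predict(tr, a = 0.3, nu = 6, phi = 0.5,
#'                         B = 0.1, lambda = 0.01, B0 = -0.2)
#' @export
phenom_predict <- function(trials, a, nu, phi, B, lambda, B0) {
  info <- .segment_info(trials)
  omega <- 2 * pi * nu / info$N
  per <- ifelse(info$adapt, a * sin(omega * info$n_ad - phi), 0)
  per + B * exp(-lambda * info$n_fit) + B0
}

# Linear basis for fixed (nu, lambda): columns sin, cos (adaptation only),
# exp, intercept. The model is linear in (a*cos(phi), -a*sin(phi), B, B0).
.phenom_basis <- function(info, nu, lambda) {
  omega <- 2 * pi * nu / info$N
  xs <- ifelse(info$adapt, sin(omega * info$n_ad), 0)
  xc <- ifelse(info$adapt, cos(omega * info$n_ad), 0)
  cbind(xs = xs, xc = xc, xe = exp(-lambda * info$n_fit), one = 1)
}

.phenom_free <- list(
  full = c("a", "nu", "phi", "B", "lambda", "B0"),
  drift = c("B", "lambda", "B0"),
  noise = "B0"
)

# RSS of the model at a named parameter vector theta over data y.
.phenom_rss_fun <- function(info, y, model) {
  n <- length(y)
  switch(model,
    full = function(theta) {
      omega <- 2 * pi * theta[["nu"]] / info$N
      per <- ifelse(info$adapt,
                    theta[["a"]] * sin(omega * info$n_ad - theta[["phi"]]), 0)
      r <- y - per - theta[["B"]] * exp(-theta[["lambda"]] * info$n_fit) -
        theta[["B0"]]
      sum(r * r)
    },
    drift = function(theta) {
      r <- y - theta[["B"]] * exp(-theta[["lambda"]] * info$n_fit) -
        theta[["B0"]]
      sum(r * r)
    },
    noise = function(theta) sum((y - theta[["B0"]])^2)
  )
}

# Grid + linear-least-squares profile stage. Returns a named start vector.
.phenom_grid_start <- function(info, y, model, priors, nu_step = 0.25) {
  lam_grid <- unique(pmin(pmax(
    c(seq(0.001, 0.05, length.out = 12), seq(0.06, 0.2, length.out = 6),
      0.3, 0.5),
    priors$lambda[1] + 1e-6), priors$lambda[2]))
  if (model == "noise") {
    return(c(B0 = mean(y)))
  }
  if (model == "drift") {
    best <- NULL
    for (lam in lam_grid) {
      X <- cbind(exp(-lam * info$n_fit), 1)
      fit <- stats::.lm.fit(X, y)
      rss <- sum(fit$residuals^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(rss = rss,
                     theta = c(B = fit$coefficients[1], lambda = lam,
                               B0 = fit$coefficients[2]))
      }
    }
    return(best$theta)
  }
  nu_grid <- seq(priors$nu[1], priors$nu[2], by = nu_step)
  best <- NULL
  for (nu in nu_grid) {
    omega <- 2 * pi * nu / info$N
    xs <- ifelse(info$adapt, sin(omega * info$n_ad), 0)
    xc <- ifelse(info$adapt, cos(omega * info$n_ad), 0)
    for (lam in lam_grid) {
      X <- cbind(xs, xc, exp(-lam * info$n_fit), 1)
      fit <- stats::.lm.fit(X, y)
      rss <- sum(fit$residuals^2)
      if (is.null(best) || rss < best$rss) {
        cf <- fit$coefficients
        best <- list(rss = rss, nu = nu, lambda = lam, cf = cf)
      }
    }
  }
  cf <- best$cf
  c(a = sqrt(cf[1]^2 + cf[2]^2), nu = best$nu,
    phi = atan2(-cf[2], cf[1]), B = cf[3], lambda = best$lambda,
    B0 = cf[4])
}

# log of the sigma-marginalized likelihood constant:
# integral over sigma of (2*pi*sigma^2)^(-n/2) exp(-RSS/(2 sigma^2)) / sigma
#   = c_n * RSS^(-n/2). Cancels in evidence ratios at equal n but kept so
# log marginal likelihoods are absolute.
.log_cn <- function(n) lgamma(n / 2) + (n / 2 - 1) * log(2) -
  (n / 2) * log(2 * pi)

#' Fit the phenomenological model to a gain series
#'
#' Bayesian fit of the six-parameter descriptive model (or of its nested
#' reductions) with a Gaussian likelihood whose noise scale is analytically
#' marginalized under a Jeffreys (1/sigma) prior, yielding a posterior
#' proportional to `RSS(theta)^(-n/2)` over the model parameters within
#' uniform box priors. The posterior mode is located by a dense grid over
#' the frequency (the posterior in `nu` is multimodal) and timescale,
#' exploiting linearity in the remaining coefficients, then polished by
#' Levenberg-Marquardt least squares. Posterior moments and the log marginal
#' likelihood are obtained by Laplace approximation at the mode.
#'
#' @param data Tibble with the trial columns of [build_session()] plus an
#'   observed-gain column `g` (at most one adaptation block; use
#'   [session_segment()] to slice a full session).
#' @param model `"full"` (lagged sinusoid + exponential baseline),
#'   `"drift"` (`a = 0`: exponential baseline only) or `"noise"` (constant
#'   mean only).
#' @param priors Prior ranges from [phenom_priors()].
#' @param nu_step Frequency-grid step (cpb) of the search stage.
#' @return An `sa_phenom_fit` object: list with `params` (tibble of posterior
#'   mean, sd and 95% interval per free parameter), `estimates` (named
#'   vector), `rss`, `sigma_hat`, `n`, `log_marglik`, `model`, `converged`,
#'   plus the data and segment info. Methods: [tidy()], [glance()],
#'   [autoplot()], `print()`.
#' @examples
#' tr <- build_session(single_block_design(6))
#' tr$g <- phenom_predict(tr, 0.3, 6, 0.5, 0.2, 0.01, -0.2) +
#'   rnorm(nrow(tr), 0, 0.05)
#' fit <- fit_phenom(tr)
#' tidy(fit)
#' @export
fit_phenom <- function(data, model = c("full", "drift", "noise"),
                       priors = phenom_priors(), nu_step = 0.25) {
  model <- match.arg(model)
  if (!"g" %in% names(data)) stop("`data` must contain a `g` column.",
                                  call. = FALSE)
  info <- .segment_info(data)
  y <- data$g
  n <- length(y)
  free <- .phenom_free[[model]]
  if (n <= length(free) + 1) {
    stop("Fewer trials than parameters.", call. = FALSE)
  }
  start <- .phenom_grid_start(info, y, model, priors, nu_step)
  rss_fun <- .phenom_rss_fun(info, y, model)
  converged <- TRUE
  if (model == "noise") {
    theta <- c(B0 = mean(y))
    rss <- rss_fun(theta)
  } else {
    resid_fun <- function(par) {
      theta <- stats::setNames(par, free)
      pred <- switch(model,
        full = {
          omega <- 2 * pi * theta[["nu"]] / info$N
          ifelse(info$adapt,
                 theta[["a"]] * sin(omega * info$n_ad - theta[["phi"]]), 0) +
            theta[["B"]] * exp(-theta[["lambda"]] * info$n_fit) +
            theta[["B0"]]
        },
        drift = theta[["B"]] * exp(-theta[["lambda"]] * info$n_fit) +
          theta[["B0"]]
      )
      y - pred
    }
    lm_fit <- minpack.lm::nls.lm(
      par = unname(start[free]), fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-15,
                                           ptol = 1e-13)
    )
    theta <- stats::setNames(lm_fit$par, free)
    rss <- sum(lm_fit$fvec^2)
    converged <- lm_fit$info %in% 1:4
    # keep the grid solution if polishing somehow went uphill
    rss_start <- rss_fun(stats::setNames(start[free], free))
    if (rss_start < rss) {
      theta <- stats::setNames(start[free], free)
      rss <- rss_start
    }
    if (model == "full" && theta[["a"]] < 0) {
      theta[["a"]] <- -theta[["a"]]
      theta[["phi"]] <- atan2(sin(theta[["phi"]] + pi),
                              cos(theta[["phi"]] + pi))
    }
    if (model == "full") {
      theta[["phi"]] <- atan2(sin(theta[["phi"]]), cos(theta[["phi"]]))
    }
  }
  lap <- .phenom_laplace(rss_fun, theta, free, rss, n, priors)
  sigma_hat <- sqrt(rss / n)
  params <- tibble::tibble(
    term = free,
    estimate = unname(theta[free]),
    sd = sqrt(lap$var),
    conf.low = unname(theta[free]) - 1.96 * sqrt(lap$var),
    conf.high = unname(theta[free]) + 1.96 * sqrt(lap$var)
  )
  structure(
    list(model = model, params = params, estimates = theta, rss = rss,
         sigma_hat = sigma_hat, n = n, log_marglik = lap$log_marglik,
         converged = converged, priors = priors, data = data, info = info),
    class = "sa_phenom_fit"
  )
}

# Laplace approximation at the posterior mode of the sigma-marginalized
# posterior kernel RSS^(-n/2) under uniform box priors. Near-unidentified
# directions (e.g. lambda when B ~ 0) are floored so that no direction
# contributes more than the widest prior width.
.phenom_laplace <- function(rss_fun, theta, free, rss, n, priors) {
  k <- length(free)
  widths <- vapply(priors[free], diff, numeric(1))
  log_vol <- sum(log(widths))
  if (rss < n * 1e-24) {
    # numerically noise-free data: degenerate posterior
    return(list(var = rep(0, k), log_marglik = Inf))
  }
  if (k == 1) {
    # constant-mean model: f(B0) = (n/2) log(S + n (B0 - mean)^2), exact
    H <- matrix(n^2 / rss, 1, 1)
  } else {
    f <- function(par) (n / 2) * log(rss_fun(stats::setNames(par, free)))
    H <- pracma::hessian(f, unname(theta[free]))
    H <- (H + t(H)) / 2
  }
  eg <- eigen(H, symmetric = TRUE)
  floor_ev <- 2 * pi / max(widths)^2
  ev <- pmax(eg$values, floor_ev)
  Hinv <- eg$vectors %*% diag(1 / ev, k) %*% t(eg$vectors)
  log_marglik <- .log_cn(n) - log_vol - (n / 2) * log(rss) +
    (k / 2) * log(2 * pi) - 0.5 * sum(log(ev))
  list(var = pmax(diag(Hinv), 0), log_marglik = log_marglik)
}

#' @export
print.sa_phenom_fit <- function(x, ...) {
  cat("<sa_phenom_fit> ", x$model, " model, n = ", x$n,
      ", rss = ", signif(x$rss, 5),
      ", sigma_hat = ", signif(x$sigma_hat, 4), "\n", sep = "")
  print(x$params)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and one-row summaries of phenomenological fits
#'
#' @param x An `sa_phenom_fit`.
#' @param ... Unused.
#' @return `tidy()`: the per-parameter posterior summary tibble;
#'   `glance()`: a one-row tibble with `model`, `n`, `rss`, `sigma_hat`,
#'   `log_marglik`, `converged`.
#' @export
tidy.sa_phenom_fit <- function(x, ...) x$params

#' @rdname tidy.sa_phenom_fit
#' @export
glance.sa_phenom_fit <- function(x, ...) {
  tibble::tibble(model = x$model, n = x$n, rss = x$rss,
                 sigma_hat = x$sigma_hat, log_marglik = x$log_marglik,
                 converged = x$converged)
}

#' @export
fitted.sa_phenom_fit <- function(object, ...) {
  th <- object$estimates
  full <- c(a = 0, nu = 1, phi = 0, B = 0, lambda = 0, B0 = 0)
  full[names(th)] <- th
  phenom_predict(object$data, full[["a"]], max(full[["nu"]], 1e-6),
                 full[["phi"]], full[["B"]], full[["lambda"]],
                 full[["B0"]])
}

#' Plot a phenomenological fit over the data
#'
#' @param object An `sa_phenom_fit`.
#' @param ... Unused.
#' @return A ggplot: observed gains (points) and the fitted curve (line),
#'   adaptation onset marked.
#' @export
autoplot.sa_phenom_fit <- function(object, ...) {
  df <- tibble::tibble(
    trial = object$info$n_fit, g = object$data$g,
    fit = fitted(object)
  )
  onset <- min(object$info$n_fit[object$info$adapt])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$g), size = 0.4,
                        alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), color = "firebrick") +
    ggplot2::geom_vline(xintercept = onset - 0.5, linetype = "dashed") +
    ggplot2::labs(x = "trial", y = "adaptation gain",
                  title = paste0("Phenomenological fit (", object$model,
                                 " model)")) +
    ggplot2::theme_minimal()
}

#' Decibel evidence between nested descriptive models
#'
#' Ten times the base-10 log of the marginal-likelihood ratio of two nested
#' models from the chain full (lagged sinusoid + exponential baseline) over
#' drift-only (`a = 0`) over noise-only (constant mean). Positive values
#' favor `model_hi`; values above 3 db indicate a significant preference.
#' The measure is antisymmetric under swapping the models and exactly
#' additive along the nested chain.
#'
#' @inheritParams fit_phenom
#' @param model_hi,model_lo Model names among `"full"`, `"drift"`,
#'   `"noise"`.
#' @return Evidence in decibels (scalar).
#' @export
evidence_db <- function(data, model_hi = "full", model_lo = "noise",
                        priors = phenom_priors(), nu_step = 0.25) {
  models <- c("full", "drift", "noise")
  if (!model_hi %in% models || !model_lo %in% models) {
    stop("Models must be nested members of {full, drift, noise}.",
         call. = FALSE)
  }
  z_hi <- fit_phenom(data, model = model_hi, priors = priors,
                     nu_step = nu_step)$log_marglik
  z_lo <- fit_phenom(data, model = model_lo, priors = priors,
                     nu_step = nu_step)$log_marglik
  10 * (z_hi - z_lo) / log(10)
}

#' Evidence report over the nested model chain
#'
#' Fits all three nested descriptive models once and reports the pairwise
#' evidences; `full_vs_noise` equals `full_vs_drift + drift_vs_noise`
#' exactly (the stacked-bar decomposition).
#'
#' @inheritParams fit_phenom
#' @return One-row tibble: `db_full_vs_drift`, `db_drift_vs_noise`,
#'   `db_full_vs_noise`, plus the three log marginal likelihoods.
#' @export
evidence_report <- function(data, priors = phenom_priors(),
                            nu_step = 0.25) {
  z <- vapply(c("full", "drift", "noise"), function(mdl) {
    fit_phenom(data, model = mdl, priors = priors,
               nu_step = nu_step)$log_marglik
  }, numeric(1))
  to_db <- function(d) 10 * d / log(10)
  db_fd <- to_db(z[["full"]] - z[["drift"]])
  db_dn <- to_db(z[["drift"]] - z[["noise"]])
  tibble::tibble(
    db_full_vs_drift = db_fd,
    db_drift_vs_noise = db_dn,
    # the stacked-bar decomposition: exactly the sum of the two segments
    db_full_vs_noise = db_fd + db_dn,
    logz_full = z[["full"]], logz_drift = z[["drift"]],
    logz_noise = z[["noise"]]
  )
}

#' Inverse-variance weighted population estimate
#'
#' Pools per-participant posterior means using weights `1/sd^2` (so that
#' noisier estimates count less); with equal sds this is the arithmetic
#' mean. Participants with `sd = 0` would dominate entirely and are
#' rejected: floor the sd before pooling.
#'
#' @param means Per-participant posterior means.
#' @param sds Per-participant posterior standard deviations (> 0).
#' @return Pooled scalar estimate.
#' @examples
#' weighted_population_estimate(c(1, 3), c(1, 1))  # 2
#' @export
weighted_population_estimate <- function(means, sds) {
  if (length(means) != length(sds)) {
    stop("`means` and `sds` must have equal length.", call. = FALSE)
  }
  if (any(sds <= 0)) {
    stop("All sds must be positive; floor zero sds before pooling ",
         "(a zero-sd participant would dominate the estimate).",
         call. = FALSE)
  }
  w <- 1 / sds^2
  sum(w * means) / sum(w)
}
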