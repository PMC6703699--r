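# Multi-start sampling boxes (bounds apply to start proposals only; the
# optimizer itself is unconstrained, so fitted values may end up outside).
.state_start_ranges <- list(
  K = c(0.001, 0.3), A = c(0.9, 1.0), m = c(-0.02, 0.02),
  D = c(-0.3, 0.05), G = c(-0.5, 0.5)  # G box is centered on the estimate
)

#' Fit a generative state-equation model to a gain series
#'
#' Nonlinear least squares of the pure forward simulation (no teacher
#' forcing): minimizes `sum_n (g(n) - x(n; theta))^2` where `x` is the
#' trajectory of [simulate_state()] driven by the stimulus gains.
#' Fixed-parameter conventions are honored (`A = 1`, `m = 0`, `D = 0` when
#' not free; `G` fixed at the five-trial initial-gain estimate unless the
#' model frees it, in which case that estimate seeds the optimizer).
#' Optimization is Levenberg-Marquardt with Latin-hypercube multi-start
#' (multimodality is real when `D` is free); the best-RSS solution is kept.
#' 95% confidence intervals come from the Jacobian linearization at the
#' optimum.
#'
#' @param data Tibble with stimulus gains `s` and observed gains `g`
#'   (e.g. [build_session()] output plus a `g` column).
#' @param model Model name (see [model_specs()]) or a one-row spec tibble.
#' @param n_starts Number of optimizer starts (1 deterministic center start
#'   plus Latin-hypercube draws; draws consume the RNG stream).
#' @param window Leading-trial window of the initial-gain estimate.
#' @param bound Divergence threshold passed to the simulator.
#' @param aicc Use the small-sample-corrected AIC instead of plain AIC.
#' @return An `sa_state_fit`: list with `spec`, `params` (full named vector
#'   `K, A, m, D, G`), `params_tbl` (tibble with estimate, se and 95% CI for
#'   free parameters), `rss`, `n`, `loglik`, `aic`, `k` (free parameters +
#'   noise scale), `predicted` (state trajectory), `converged`, `unstable`.
#'   Methods: [tidy()], [glance()], [autoplot()], `print()`.
#' @examples
#' tr <- build_session(single_block_design(6))
#' tr$g <- simulate_state(tr$s, K = 0.02, A = 0.99, m = -0.004, G = 0)
#' fit <- fit_state_model(tr, "KAm", n_starts = 2)
#' glance(fit)
#' @export
fit_state_model <- function(data, model, n_starts = 8, window = 5,
                            bound = 1e6, aicc = FALSE) {
  spec <- if (is.character(model)) model_spec(model) else model
  stopifnot(is.data.frame(spec), nrow(spec) == 1)
  if (!all(c("s", "g") %in% names(data))) {
    stop("`data` must carry `s` and `g` columns.", call. = FALSE)
  }
  s <- as.numeric(data$s)
  g <- as.numeric(data$g)
  n <- length(g)
  ghat <- initial_gain_estimate(g, window = window)

  free <- c("K", if (spec$free_A) "A", if (spec$free_m) "m",
            if (spec$free_D) "D", if (spec$free_G) "G")
  k_free <- length(free)
  fixed <- c(K = NA_real_, A = 1, m = 0, D = 0, G = ghat)

  make_full <- function(par) {
    full <- fixed
    full[free] <- par
    full
  }
  resid_fun <- function(par) {
    th <- make_full(par)
    x <- .sim_state_cpp(th[["K"]], th[["A"]], th[["m"]], th[["D"]],
                        th[["G"]], s, bound)
    g - as.numeric(x)
  }

  starts <- .state_starts(free, ghat, n_starts)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[i, ], fn = resid_fun,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-12)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (!is.null(best)) {
    # polish: a fresh trust region from the best solution tightens the
    # optimum to machine precision on noise-free data
    polish <- tryCatch(
      minpack.lm::nls.lm(
        par = best$fit$par, fn = resid_fun,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                             ptol = 1e-15)
      ),
      error = function(e) NULL
    )
    if (!is.null(polish) && sum(polish$fvec^2) <= best$rss) {
      best <- list(fit = polish, rss = sum(polish$fvec^2))
    }
  }
  if (is.null(best)) {
    return(structure(
      list(spec = spec, params = fixed, params_tbl = NULL, rss = Inf,
           n = n, loglik = -Inf, aic = Inf, k = k_free + 1,
           predicted = rep(NA_real_, n), converged = FALSE,
           unstable = TRUE, data = data),
      class = "sa_state_fit"
    ))
  }
  theta <- make_full(best$fit$par)
  x <- .sim_state_cpp(theta[["K"]], theta[["A"]], theta[["m"]],
                      theta[["D"]], theta[["G"]], s, bound)
  unstable <- isTRUE(attr(x, "unstable"))
  rss <- best$rss
  k <- k_free + 1  # + Gaussian noise scale
  loglik <- -n / 2 * (log(2 * pi * rss / n) + 1)
  aic <- n * log(rss / n) + 2 * k
  if (aicc) aic <- aic + 2 * k * (k + 1) / (n - k - 1)
  params_tbl <- .state_ci(best$fit, free, rss, n)
  structure(
    list(spec = spec, params = theta, params_tbl = params_tbl, rss = rss,
         n = n, loglik = loglik, aic = aic, k = k,
         predicted = as.numeric(x),
         converged = best$fit$info %in% 1:4 && !unstable,
         unstable = unstable, data = data),
    class = "sa_state_fit"
  )
}

# Deterministic center start + Latin-hypercube starts over the sampling
# boxes; matrix with one start per row, columns in `free` order.
.state_starts <- function(free, ghat, n_starts) {
  rng <- .state_start_ranges
  rng$G <- ghat + rng$G
  center <- c(K = 0.05, A = 0.99, m = 0, D = -0.05, G = ghat)
  starts <- matrix(center[free], nrow = 1,
                   dimnames = list(NULL, free))
  if (n_starts > 1) {
    u <- lhs::randomLHS(n_starts - 1, length(free))
    lo <- vapply(rng[free], `[`, numeric(1), 1)
    hi <- vapply(rng[free], `[`, numeric(1), 2)
    extra <- sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
    colnames(extra) <- free
    starts <- rbind(starts, extra)
  }
  starts
}

# Jacobian-linearization 95% intervals at the optimum; rank-deficient
# Jacobians yield NA intervals flagged as unidentifiable.
.state_ci <- function(fit, free, rss, n) {
  k_free <- length(free)
  df <- max(n - k_free, 1)
  sigma2 <- rss / df
  vc <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, k_free) else sqrt(pmax(diag(vc), 0))
  tq <- stats::qt(0.975, df)
  tibble::tibble(
    term = free,
    estimate = unname(fit$par),
    se = se,
    conf.low = unname(fit$par) - tq * se,
    conf.high = unname(fit$par) + tq * se,
    identifiable = !is.na(se)
  )
}

#' @export
print.sa_state_fit <- function(x, ...) {
  cat("<sa_state_fit> model ", x$spec$name, " (group ", x$spec$group,
      "), n = ", x$n, "\n", sep = "")
  cat("  rss = ", signif(x$rss, 5), ", AIC = ", signif(x$aic, 6),
      ", converged = ", x$converged, "\n", sep = "")
  if (!is.null(x$params_tbl)) print(x$params_tbl)
  invisible(x)
}

#' Tidy and one-row summaries of state-equation fits
#'
#' @param x An `sa_state_fit`.
#' @param ... Unused.
#' @return `tidy()`: tibble with estimate, se and 95% CI per free parameter
#'   (fixed parameters carry no interval); `glance()`: one-row tibble with
#'   `model`, `group`, `n`, `rss`, `loglik`, `aic`, `k`, `converged`,
#'   `unstable`.
#' @export
tidy.sa_state_fit <- function(x, ...) x$params_tbl

#' @rdname tidy.sa_state_fit
#' @export
glance.sa_state_fit <- function(x, ...) {
  tibble::tibble(model = x$spec$name, group = x$spec$group, n = x$n,
                 rss = x$rss, loglik = x$loglik, aic = x$aic, k = x$k,
                 converged = x$converged, unstable = x$unstable)
}

#' Plot a state-equation fit over the data
#'
#' @param object An `sa_state_fit`.
#' @param ... Unused.
#' @return A ggplot of observed gains and the fitted latent trajectory.
#' @export
autoplot.sa_state_fit <- function(object, ...) {
  df <- tibble::tibble(trial = seq_len(object$n), g = object$data$g,
                       x = object$predicted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$g), size = 0.4,
                        alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$x), color = "steelblue") +
    ggplot2::labs(x = "trial", y = "adaptation gain",
                  title = paste0("State-equation fit (", object$spec$name,
                                 ")")) +
    ggplot2::theme_minimal()
}

#' Fit the whole sixteen-model family to one gain series
#'
#' @inheritParams fit_state_model
#' @param specs Spec tibble (defaults to the full family).
#' @return A tibble with one row per model: the [glance()] columns plus a
#'   `fit` list-column and the Akaike `weight` across the family.
#' @export
fit_state_models <- function(data, specs = model_specs(), n_starts = 8,
                             window = 5, aicc = FALSE) {
  fits <- purrr::map(seq_len(nrow(specs)), function(i) {
    fit_state_model(data, specs[i, ], n_starts = n_starts, window = window,
                    aicc = aicc)
  })
  out <- dplyr::bind_rows(purrr::map(fits, glance))
  out$fit <- fits
  out$weight <- akaike_weights(out$aic)
  out
}

#' Akaike weights across a model set
#'
#' `w_i = exp(-Delta_i/2) / sum_j exp(-Delta_j/2)` with
#' `Delta_i = AIC_i - min(AIC)`. Interpreted as relative support for each
#' model given the data; weights sum to 1.
#'
#' @param aic Numeric vector of AIC values (non-finite entries get zero
#'   weight).
#' @return Numeric weight vector summing to 1.
#' @examples
#' akaike_weights(c(100, 102))  # ~ (0.731, 0.269)
#' @export
akaike_weights <- function(aic) {
  if (is.data.frame(aic)) aic <- aic$aic
  delta <- aic - min(aic[is.finite(aic)])
  w <- exp(-delta / 2)
  w[!is.finite(aic)] <- 0
  w / sum(w)
}

#' Average Akaike weights across participants
#'
#' Element-wise arithmetic mean of per-participant weight vectors (rows of
#' a matrix, a list of vectors, or a long tibble with `participant`,
#' `model`, `weight` columns). Because each participant's weights sum to 1,
#' the average does too.
#'
#' @param w Participants-by-models weight matrix, list of equal-length
#'   vectors, or long tibble.
#' @return Tibble with `model` and averaged `weight`.
#' @export
average_weights <- function(w) {
  if (is.data.frame(w)) {
    out <- dplyr::summarise(dplyr::group_by(w, .data$model),
                            weight = mean(.data$weight), .groups = "drop")
    return(out)
  }
  if (is.list(w)) w <- do.call(rbind, w)
  mw <- colMeans(w)
  tibble::tibble(
    model = if (is.null(colnames(w))) paste0("model_", seq_along(mw))
            else colnames(w),
    weight = unname(mw)
  )
}

#' Identify the best model from averaged weights
#'
#' Ties are broken by fewer free parameters, then lexicographic name.
#'
#' @param weights Tibble with `model` and `weight` (names must be family
#'   names from [model_specs()]).
#' @return The winning model name (scalar character).
#' @export
best_model <- function(weights) {
  specs <- model_specs()
  k_free <- stats::setNames(nchar(specs$name), specs$name)
  ord <- order(-weights$weight, k_free[weights$model], weights$model)
  weights$model[ord[1]]
}

#' Aggregate averaged model weights into the four model groups
#'
#' @param weights Tibble with `model` and `weight`.
#' @return Tibble with `group` (I-IV) and summed `weight`.
#' @export
group_weights <- function(weights) {
  specs <- model_specs()
  grp <- stats::setNames(specs$group, specs$name)
  w <- dplyr::mutate(weights, group = grp[.data$model])
  dplyr::summarise(dplyr::group_by(w, .data$group),
                   weight = sum(.data$weight), .groups = "drop")
}
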