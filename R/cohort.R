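# Run code under a temporary RNG state so seeded generators do not disturb
# the caller's stream.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Deterministic child seed for one observer
#'
#' One master seed spawns per-observer seeds as
#' `(master * 1000003 + replicate * 1000 + participant) mod (2^31 - 1)`,
#' so cohorts are extensible (adding participants or replicates never
#' reshuffles existing ones) and every seed stays in 32-bit range.
#'
#' @param master Master seed (integer).
#' @param participant Participant index (1-based).
#' @param replicate Replicate index (1-based).
#' @return Integer seed.
#' @export
child_seed <- function(master, participant, replicate = 1) {
  as.integer((as.numeric(master) * 1000003 + replicate * 1000 +
                participant) %% (2^31 - 1))
}

#' Default observation-noise level per adaptation type
#'
#' The generative learners are noise-free; i.i.d. Gaussian observation
#' noise on the gain stands in for saccadic and measurement variability.
#' Global adaptation carries more measurement noise than Two-way, so its
#' default sigma is larger.
#'
#' @param adaptation_type `"two-way"` or `"global"`.
#' @return Noise standard deviation (gain units).
#' @export
default_sigma <- function(adaptation_type = c("two-way", "global")) {
  switch(match.arg(adaptation_type), "two-way" = 0.08, "global" = 0.15)
}

#' Default truth-parameter ranges for synthetic cohorts
#'
#' Participant-level parameters are drawn uniformly from these ranges.
#' Learning rates follow the single-error scales reported for Two-way
#' (0.01-0.035) and Global (0.005-0.015) adaptation; double-error models
#' use an order-of-magnitude larger `K` with a similar-magnitude negative
#' `D` (Two-way), scaled down for Global so that `K + D` stays positive
#' and the learner stable. Retention sits just below 1 and the drift is a
#' small negative number producing baseline asymptotes of a few tenths of
#' the disturbance amplitude.
#'
#' @param model Truth model name (family member; `D`-free models get the
#'   double-error ranges).
#' @param adaptation_type `"two-way"` or `"global"`.
#' @return Named list of length-2 ranges for `K`, `A`, `m`, `D`, `G`.
#' @export
truth_ranges <- function(model = "KAm",
                         adaptation_type = c("two-way", "global")) {
  adaptation_type <- match.arg(adaptation_type)
  spec <- model_spec(model)
  two_way <- adaptation_type == "two-way"
  K <- if (spec$free_D) {
    if (two_way) c(0.12, 0.18) else c(0.06, 0.10)
  } else {
    if (two_way) c(0.010, 0.035) else c(0.005, 0.015)
  }
  D <- if (spec$free_D) {
    if (two_way) c(-0.16, -0.10) else c(-0.05, -0.02)
  } else c(0, 0)
  list(
    K = K,
    A = if (spec$free_A) c(0.985, 1.0) else c(1, 1),
    m = if (spec$free_m) c(-0.008, -0.003) else c(0, 0),
    D = D,
    G = c(-0.15, 0.05)
  )
}

#' Generate one synthetic observer
#'
#' Simulates the latent state of a chosen generative model over a session
#' and overlays i.i.d. Gaussian observation noise:
#' `g(n) = x(n) + eps(n)`, `eps ~ N(0, sigma^2)`, drawn from a seeded
#' generator. The latent trajectory is kept (column `x`) for oracle use.
#'
#' @param design An [session_design()].
#' @param params Named vector/list with `K`, `A`, `m`, `D`, `G` (defaults
#'   `A = 1`, `m = 0`, `D = 0`, `G = 0`).
#' @param sigma Observation-noise sd (gain units, >= 0); default per the
#'   design's adaptation type ([default_sigma()]).
#' @param seed Seed for the noise draw (`NULL` uses the current stream).
#' @return Trial tibble with added `x` (latent state) and `g` (observed
#'   gain) columns.
#' @examples
#' obs <- generate_observer(single_block_design(6),
#'                          c(K = 0.02, A = 0.99, m = -0.004, G = 0),
#'                          sigma = 0.1, seed = 1)
#' @export
generate_observer <- function(design, params, sigma = NULL, seed = NULL) {
  prm <- c(K = NA_real_, A = 1, m = 0, D = 0, G = 0)
  params <- unlist(params)
  prm[names(params)] <- params
  if (is.na(prm[["K"]])) stop("`params` must include K.", call. = FALSE)
  if (!is_stable(prm[["K"]], prm[["A"]], prm[["D"]])) {
    stop("Unstable truth parameters (characteristic root on or outside ",
         "the unit circle).", call. = FALSE)
  }
  if (is.null(sigma)) sigma <- default_sigma(design$adaptation_type)
  if (sigma < 0) stop("`sigma` must be non-negative.", call. = FALSE)
  trials <- build_session(design)
  x <- simulate_state(trials$s, prm[["K"]], prm[["A"]], prm[["m"]],
                      prm[["D"]], prm[["G"]])
  eps <- if (is.null(seed)) {
    stats::rnorm(nrow(trials), 0, sigma)
  } else {
    .with_seed(seed, stats::rnorm(nrow(trials), 0, sigma))
  }
  trials$x <- as.numeric(x)
  trials$g <- trials$x + eps
  trials
}

#' Generate a seeded synthetic cohort
#'
#' Draws participant-level truth parameters uniformly from per-parameter
#' ranges (scalars fix a parameter exactly), rejecting unstable draws, and
#' generates one observer per participant. Identical configuration and
#' master seed reproduce the cohort exactly.
#'
#' @param design An [session_design()].
#' @param model Truth model name; parameters that the model fixes are held
#'   at their conventions regardless of `truth`.
#' @param truth Named list of parameter values or length-2 ranges;
#'   defaults to [truth_ranges()] for the model and adaptation type.
#' @param sigma Observation-noise sd; default per adaptation type.
#' @param n_participants Cohort size.
#' @param seed Master seed.
#' @param replicate Replicate index entering the child-seed derivation.
#' @return A manifest tibble with one row per observer: `participant`,
#'   `seed`, truth parameters `K`, `A`, `m`, `D`, `G`, `sigma`, and a
#'   `trials` list-column of observer tibbles from [generate_observer()].
#' @export
generate_cohort <- function(design, model = "KAm", truth = NULL,
                            sigma = NULL, n_participants = 13, seed = 1,
                            replicate = 1) {
  spec <- model_spec(model)
  ranges <- truth_ranges(model, design$adaptation_type)
  if (!is.null(truth)) {
    for (nm in names(truth)) {
      v <- truth[[nm]]
      ranges[[nm]] <- if (length(v) == 1) c(v, v) else v
    }
  }
  # fixed-parameter conventions always win over supplied ranges
  if (!spec$free_A) ranges$A <- c(1, 1)
  if (!spec$free_m) ranges$m <- c(0, 0)
  if (!spec$free_D) ranges$D <- c(0, 0)
  if (is.null(sigma)) sigma <- default_sigma(design$adaptation_type)

  rows <- purrr::map(seq_len(n_participants), function(i) {
    sd_i <- child_seed(seed, i, replicate)
    prm <- .with_seed(sd_i, .draw_stable_params(ranges))
    obs <- generate_observer(design, prm, sigma = sigma,
                             seed = child_seed(seed, i, replicate) + 1L)
    tibble::tibble(
      participant = i, seed = sd_i,
      K = prm[["K"]], A = prm[["A"]], m = prm[["m"]], D = prm[["D"]],
      G = prm[["G"]], sigma = sigma, trials = list(obs)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "model") <- model
  attr(out, "design") <- design
  out
}

.draw_stable_params <- function(ranges, max_tries = 100) {
  draw1 <- function(r) if (r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])
  for (i in seq_len(max_tries)) {
    prm <- vapply(ranges, draw1, numeric(1))
    if (is_stable(prm[["K"]], prm[["A"]], prm[["D"]])) return(prm)
  }
  stop("Could not draw stable truth parameters from the given ranges.",
       call. = FALSE)
}

#' Parameter-recovery and model-selection experiment
#'
#' End-to-end validation harness: generates `n_replicates` seeded cohorts
#' from a truth model, refits the truth model to every observer
#' (truth-vs-estimate comparison and CI coverage), and optionally fits the
#' whole sixteen-model family to run Akaike-weight selection per cohort.
#' Non-convergence propagates as per-run flags; it never aborts the cohort.
#'
#' @inheritParams generate_cohort
#' @param n_replicates Number of independent cohort replicates.
#' @param fit_family Also fit all 16 models and run selection (slower).
#' @param n_starts Optimizer starts per fit.
#' @param window Initial-gain estimate window.
#' @return An `sa_recovery` object: list with `estimates` (tibble: one row
#'   per replicate x participant x free parameter with truth, estimate,
#'   CI and coverage flag), `summary` (per-parameter bias, RMSE, coverage
#'   rate), `selection` (per-replicate averaged weights, winning model and
#'   group; `NULL` unless `fit_family`), `config`.
#' @export
recovery_experiment <- function(design, model = "KAm", truth = NULL,
                                sigma = NULL, n_participants = 13,
                                n_replicates = 20, seed = 1,
                                fit_family = FALSE, n_starts = 8,
                                window = 5) {
  spec <- model_spec(model)
  free <- c("K", if (spec$free_A) "A", if (spec$free_m) "m",
            if (spec$free_D) "D", if (spec$free_G) "G")
  est_rows <- list()
  sel_rows <- list()
  for (r in seq_len(n_replicates)) {
    cohort <- generate_cohort(design, model, truth, sigma, n_participants,
                              seed, replicate = r)
    wmat <- NULL
    for (i in seq_len(nrow(cohort))) {
      obs <- cohort$trials[[i]]
      fit_seed <- child_seed(seed, i, r) + 2L
      fit <- .with_seed(fit_seed,
                        fit_state_model(obs, model, n_starts = n_starts,
                                        window = window))
      tb <- fit$params_tbl
      truth_i <- unlist(cohort[i, c("K", "A", "m", "D", "G")])
      est_rows[[length(est_rows) + 1]] <- tibble::tibble(
        replicate = r, participant = i, term = tb$term,
        truth = unname(truth_i[tb$term]), estimate = tb$estimate,
        conf.low = tb$conf.low, conf.high = tb$conf.high,
        covered = !is.na(tb$conf.low) &
          truth_i[tb$term] >= tb$conf.low &
          truth_i[tb$term] <= tb$conf.high,
        converged = fit$converged
      )
      if (fit_family) {
        fam <- .with_seed(fit_seed + 1L,
                          fit_state_models(obs, n_starts = n_starts,
                                           window = window))
        w <- stats::setNames(fam$weight, fam$model)
        wmat <- rbind(wmat, w)
      }
    }
    if (fit_family) {
      avg <- average_weights(wmat)
      gw <- group_weights(avg)
      sel_rows[[length(sel_rows) + 1]] <- tibble::tibble(
        replicate = r,
        best_model = best_model(avg),
        best_group = gw$group[which.max(gw$weight)],
        weights = list(avg), group_weights = list(gw)
      )
    }
  }
  estimates <- dplyr::bind_rows(est_rows)
  summary_tbl <- dplyr::summarise(
    dplyr::group_by(estimates, .data$term),
    bias = mean(.data$estimate - .data$truth),
    rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
    coverage = mean(.data$covered),
    .groups = "drop"
  )
  structure(
    list(
      estimates = estimates, summary = summary_tbl,
      selection = if (fit_family) dplyr::bind_rows(sel_rows) else NULL,
      config = list(model = model, truth = truth, sigma = sigma,
                    n_participants = n_participants,
                    n_replicates = n_replicates, seed = seed,
                    free = free, design = design)
    ),
    class = "sa_recovery"
  )
}

#' @export
print.sa_recovery <- function(x, ...) {
  cat("<sa_recovery> truth model ", x$config$model, ", ",
      x$config$n_replicates, " replicates x ",
      x$config$n_participants, " participants\n", sep = "")
  print(x$summary)
  if (!is.null(x$selection)) {
    tab <- table(x$selection$best_group)
    cat("winning group by replicate: ",
        paste(names(tab), tab, sep = ":", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot recovery estimates against truth
#'
#' @param object An `sa_recovery`.
#' @param ... Unused.
#' @return A ggplot of estimate vs truth per free parameter.
#' @export
autoplot.sa_recovery <- function(object, ...) {
  ggplot2::ggplot(object$estimates,
                  ggplot2::aes(x = .data$truth, y = .data$estimate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "truth", y = "estimate",
                  title = "Parameter recovery") +
    ggplot2::theme_minimal()
}
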