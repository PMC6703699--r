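#' Baseline asymptote of the adaptation gain
#'
#' At large trial number the baseline of the gain approaches
#' `B0 = m / (1 - (A - (K + D)))`. A non-zero asymptote requires a non-zero
#' drift `m`; when `A = 1` this reduces to `m/(K+D)` (or `m/K` when
#' `D = 0`).
#'
#' @param K,A,m,D Generative parameters.
#' @return Scalar asymptote (gain units).
#' @examples
#' asymptote(K = 0.02, A = 1, m = -0.004)  # -0.2
#' @export
asymptote <- function(K, A = 1, m = 0, D = 0) {
  den <- 1 - (A - (K + D))
  if (abs(den) < .Machine$double.eps^0.5) {
    stop("Marginally stable parameterization: 1 - (A - (K + D)) is zero; ",
         "no finite asymptote exists.", call. = FALSE)
  }
  m / den
}

#' Decay modes and timescale of the baseline
#'
#' The baseline relaxes through the modes `e^(-lambda+-) =
#' (1/2) * ((A-K) +- sqrt((A-K)^2 - 4D))`, the roots of
#' `r^2 - (A-K) r + D = 0`. For `D = 0` there is a single mode
#' `e^(-lambda) = A - K`. With `D < 0` the subtraction root is negative and
#' small: it decays fast, alternating in sign, and merely modulates the
#' dominant monotonic decay. The dominant timescale is `-log` of the
#' largest-magnitude root; when the discriminant is negative the roots are
#' complex and the dominant timescale is `-log` of their modulus, with
#' `oscillatory = TRUE`.
#'
#' @param K,A,D Generative parameters.
#' @return A list with `roots` (the mode multipliers — one for `D = 0`,
#'   two otherwise; complex if
#'   oscillatory), `dominant_root`, `dominant_lambda` (1/trials),
#'   `oscillatory` flag, and `stable` flag.
#' @examples
#' decay_timescales(K = 0.02, A = 1)$dominant_lambda  # -log(0.98)
#' @export
decay_timescales <- function(K, A = 1, D = 0) {
  # D = 0 degenerates to a first-order recursion: a single mode A - K
  r <- if (D == 0) A - K else characteristic_roots(K, A, D)
  oscillatory <- is.complex(r)
  dom <- r[which.max(Mod(r))]
  list(
    roots = r,
    dominant_root = dom,
    dominant_lambda = -log(Mod(dom)),
    oscillatory = oscillatory,
    stable = all(Mod(r) < 1)
  )
}

#' Periodic response of the state equation to a sinusoidal stimulus
#'
#' For a unit sinusoidal stimulus gain `s(n) = sin(omega*n)` the stable
#' steady-state of the learner is `a * sin(omega*n - (phi + varphi))`. The
#' bare lag `phi` and the magnitude `R` come from the recursion's
#' denominator,
#' `cos(phi) = (cos(omega) - (A - K - D*cos(omega))) / R`,
#' `sin(phi) = ((1 - D) * sin(omega)) / R`;
#' double error sampling contributes the numerator magnitude
#' `Q = sqrt((K + D*cos(omega))^2 + (D*sin(omega))^2)` and the extra lag
#' `varphi` with `cos(varphi) = (K + D*cos(omega))/Q`,
#' `sin(varphi) = D*sin(omega)/Q`. The amplitude is `a = Q/R`, reducing to
#' `K/R` when `D = 0` (and then `varphi = 0`). The observed behavioral lag
#' corresponds to `phi + varphi`.
#'
#' @param K,A,D Generative parameters (stable).
#' @param omega Angular frequency per trial, `2*pi*f/N`, in `(0, pi]`.
#' @return A tibble with columns `a`, `phi`, `varphi`, `total_lag`
#'   (radians), `lag_trials` (`total_lag/omega`), `R`, `Q`, `omega`.
#' @examples
#' periodic_response(K = 0.02, A = 1, D = 0, omega = 2 * pi * 6 / 384)
#' @export
periodic_response <- function(K, A = 1, D = 0, omega) {
  if (any(omega <= 0 | omega > pi)) {
    stop("`omega` must lie in (0, pi].", call. = FALSE)
  }
  co <- cos(omega); si <- sin(omega)
  re_den <- co - (A - K - D * co)
  im_den <- (1 - D) * si
  R <- sqrt(re_den^2 + im_den^2)
  if (any(R < .Machine$double.eps^0.5)) {
    stop("Degenerate (resonant) parameterization: R = 0.", call. = FALSE)
  }
  phi <- atan2(im_den, re_den)
  Q <- sqrt((K + D * co)^2 + (D * si)^2)
  varphi <- atan2(D * si, K + D * co)
  tibble::tibble(
    a = Q / R, phi = phi, varphi = varphi,
    total_lag = phi + varphi, lag_trials = (phi + varphi) / omega,
    R = R, Q = Q, omega = omega
  )
}

#' Phenomenological parameters predicted from generative ones
#'
#' Convenience wrapper combining [periodic_response()], [asymptote()] and
#' [decay_timescales()]: the closed-form phenomenology (periodic amplitude
#' and total lag, baseline asymptote and dominant decay timescale) implied
#' by a generative parameter set at a given stimulus frequency. The decay
#' amplitude `B` depends strongly on the initial condition and is not
#' predicted.
#'
#' @param K,A,m,D Generative parameters.
#' @param f Stimulus frequency in cycles per block.
#' @param N Adaptation block length in trials.
#' @return One-row tibble: `f`, `omega`, `a`, `total_lag`, `lag_trials`,
#'   `B0`, `dominant_lambda`, `oscillatory`.
#' @examples
#' predict_phenom_params(K = 0.15, A = 0.99, m = -0.004, D = -0.13, f = 6)
#' @export
predict_phenom_params <- function(K, A = 1, m = 0, D = 0, f, N = 384) {
  omega <- 2 * pi * f / N
  pr <- periodic_response(K, A, D, omega)
  ts <- decay_timescales(K, A, D)
  tibble::tibble(
    f = f, omega = omega,
    a = pr$a, total_lag = pr$total_lag, lag_trials = pr$lag_trials,
    B0 = asymptote(K, A, m, D),
    dominant_lambda = ts$dominant_lambda,
    oscillatory = ts$oscillatory
  )
}
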