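#' The sixteen-member generative model family
#'
#' Every model contains the learning rate `K` (learning from the last
#' feedback error is assumed obligatory). The persistence rate `A`, the
#' drift `m`, the next-to-last-error rate `D` and the initial condition `G`
#' are each either free or fixed (`A = 1`, `m = 0`, `D = 0`; `G` fixed means
#' estimated as the mean of the first five gain values). Crossing the four
#' optional parameters yields sixteen models, grouped by the presence of
#' `m` and `D`:
#' group I (neither), II (`m` only), III (`D` only), IV (both).
#'
#' @return A tibble with one row per model: `name` (canonical `K[A][m][D][G]`
#'   string), `free_A`, `free_m`, `free_D`, `free_G`, `group` (`"I"`..`"IV"`),
#'   ordered by group then name.
#' @examples
#' model_specs()
#' @export
model_specs <- function() {
  grid <- tidyr::expand_grid(
    free_A = c(FALSE, TRUE), free_m = c(FALSE, TRUE),
    free_D = c(FALSE, TRUE), free_G = c(FALSE, TRUE)
  )
  grid$name <- paste0(
    "K",
    ifelse(grid$free_A, "A", ""), ifelse(grid$free_m, "m", ""),
    ifelse(grid$free_D, "D", ""), ifelse(grid$free_G, "G", "")
  )
  grid$group <- dplyr::case_when(
    !grid$free_m & !grid$free_D ~ "I",
    grid$free_m & !grid$free_D ~ "II",
    !grid$free_m & grid$free_D ~ "III",
    TRUE ~ "IV"
  )
  out <- dplyr::arrange(grid, .data$group, .data$name)
  dplyr::select(out, "name", "free_A", "free_m", "free_D", "free_G", "group")
}

#' Look up one model specification by name
#'
#' @param name Canonical model name, e.g. `"K"`, `"KAm"`, `"KAmDG"`.
#' @return A one-row tibble as in [model_specs()].
#' @export
model_spec <- function(name) {
  specs <- model_specs()
  hit <- specs[specs$name == name, , drop = FALSE]
  if (nrow(hit) == 0) {
    stop("Unknown model name \"", name, "\"; see `model_specs()`.",
         call. = FALSE)
  }
  hit
}

#' Complete a parameter set against a model specification
#'
#' Enforces the fixed-parameter conventions: `A = 1`, `m = 0`, `D = 0` when
#' not free. `G` must always be supplied (when the spec has `free_G = FALSE`
#' it is the five-trial initial-gain estimate, computed by the caller).
#'
#' @param spec One-row tibble from [model_spec()].
#' @param K,A,m,D,G Parameter values; fixed ones may be omitted.
#' @return Named numeric vector `c(K, A, m, D, G)`.
#' @export
generative_params <- function(spec, K, A = NULL, m = NULL, D = NULL, G) {
  stopifnot(nrow(spec) == 1)
  A <- if (spec$free_A) A else 1
  m <- if (spec$free_m) m else 0
  D <- if (spec$free_D) D else 0
  if (is.null(A) || is.null(m) || is.null(D)) {
    stop("Free parameters of model ", spec$name, " must all be supplied.",
         call. = FALSE)
  }
  prm <- c(K = K, A = A, m = m, D = D, G = G)
  if (any(!is.finite(prm))) {
    stop("Non-finite generative parameters.", call. = FALSE)
  }
  prm
}

#' Initial-gain estimate from the first trials of a gain series
#'
#' The state variable is internal, so its initial value is approximated by
#' the average of the first few observed gains (five by default). Used as
#' the fixed `G` in models without a free initial condition, and as the
#' optimizer start for `G` otherwise.
#'
#' @param g Numeric gain series (or a tibble with a `g` column).
#' @param window Number of leading trials to average (default 5).
#' @return Scalar gain value.
#' @examples
#' initial_gain_estimate(c(0, 0.5, -0.5, 0.2, -0.2, 9))  # 0
#' @export
initial_gain_estimate <- function(g, window = 5) {
  if (is.data.frame(g)) g <- g$g
  if (length(g) == 0) stop("Empty gain series.", call. = FALSE)
  if (length(g) < window) {
    stop("Gain series shorter than the averaging window (", window, ").",
         call. = FALSE)
  }
  mean(g[seq_len(window)])
}

#' Forward-simulate the state equation
#'
#' Iterates the noise-free delta-rule learner
#' `x(n+1) = A*x(n) + K*(s(n) - x(n)) + m + D*(s(n-1) - x(n-1))`
#' over the stimulus gains of a trial series, with `x(1) = G` and the
#' start-up convention `s(0) = 0`, `x(0) = x(1)`. Divergence (|x| beyond
#' `bound`) is reported through the `"unstable"` attribute rather than as an
#' error, so that optimizers can penalize unstable proposals.
#'
#' @param trials A trial tibble from [build_session()], or a numeric vector
#'   of stimulus gains.
#' @param K,A,m,D,G Generative parameters (see [generative_params()]).
#' @param bound Divergence threshold on |x| (default `1e6`).
#' @return If `trials` is a tibble, the tibble with an added `x_pred` column
#'   (and attribute `"unstable"`); if a numeric vector, the numeric state
#'   trajectory with the same attribute.
#' @examples
#' tr <- build_session(single_block_design(6))
#' x <- simulate_state(tr$s, K = 0.02, A = 1, m = 0, D = 0, G = 0)
#' @export
simulate_state <- function(trials, K, A = 1, m = 0, D = 0, G = 0,
                           bound = 1e6) {
  prm <- c(K, A, m, D, G)
  if (any(!is.finite(prm))) {
    stop("Non-finite generative parameters.", call. = FALSE)
  }
  s <- if (is.data.frame(trials)) trials$s else trials
  x <- .sim_state_cpp(K, A, m, D, G, as.numeric(s), bound)
  unstable <- attr(x, "unstable")
  if (is.data.frame(trials)) {
    out <- trials
    out$x_pred <- as.numeric(x)
    attr(out, "unstable") <- unstable
    out
  } else {
    x
  }
}

#' Stability of a generative parameterization
#'
#' The homogeneous recursion is `x(n+1) = (A-K) x(n) - D x(n-1)`; the
#' parameterization is stable iff both roots of
#' `r^2 - (A-K) r + D = 0` lie strictly inside the unit circle.
#'
#' @param K,A,D Generative parameters.
#' @return `TRUE`/`FALSE`.
#' @examples
#' is_stable(K = 0.15, A = 0.99, D = -0.13)
#' @export
is_stable <- function(K, A = 1, D = 0) {
  r <- characteristic_roots(K, A, D)
  all(Mod(r) < 1)
}

#' @rdname is_stable
#' @return `characteristic_roots()`: the two (possibly complex) roots.
#' @export
characteristic_roots <- function(K, A = 1, D = 0) {
  b <- A - K
  disc <- as.complex(b^2 - 4 * D)
  r <- c(b + sqrt(disc), b - sqrt(disc)) / 2
  if (all(Im(r) == 0)) r <- Re(r)
  r
}

#' Two-learner decomposition of the double-error-sampling model
#'
#' Rewrites the double-error learner (with `m = 0`) as two single-feedback
#' channels: `X+` learns the half-sum of the last two stimulus samples with
#' rate `kappa = K + D` (slow channel), `X-` learns the half-difference — a
#' discrete stimulus derivative — with rate `eta = K - D` (fast channel).
#' The decomposition is exact: `x(n) = X+(n) + X-(n)` and
#' `s(n) = S+(n) + S-(n)` trial by trial (start-up uses `s(0) = 0`,
#' `x(0) = x(1)`).
#'
#' @param trials Trial tibble (column `s`) aligned with the trajectory.
#' @param x State trajectory (numeric, or tibble column `x_pred`).
#' @param K,D Learning rates of the double-error model.
#' @return A tibble with columns `trial`, `s`, `x`, `S_plus`, `S_minus`,
#'   `X_plus`, `X_minus`, and attributes `kappa`, `eta`.
#' @export
two_learner_view <- function(trials, x, K, D) {
  s <- if (is.data.frame(trials)) trials$s else trials
  if (is.data.frame(x)) x <- x$x_pred
  if (length(s) != length(x)) {
    stop("Trajectory and trial series are not aligned.", call. = FALSE)
  }
  s_lag <- c(0, s[-length(s)])
  x_lag <- c(x[1], x[-length(x)])
  out <- tibble::tibble(
    trial = seq_along(s), s = s, x = x,
    S_plus = (s + s_lag) / 2, S_minus = (s - s_lag) / 2,
    X_plus = (x + x_lag) / 2, X_minus = (x - x_lag) / 2
  )
  attr(out, "kappa") <- K + D
  attr(out, "eta") <- K - D
  out
}
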