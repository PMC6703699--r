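#' Define a sinusoidal double-step session design
#'
#' A session is an ordered sequence of blocks, each either a non-adaptation
#' block (zero intra-saccadic step, ISS) or an adaptation block in which the
#' ISS varies as a sine function of the within-block trial number. The ISS
#' amplitude `P` is expressed relative to the pre-saccadic target step
#' `preTP`, giving the dimensionless stimulus amplitude ratio `p = P/preTP`.
#'
#' Frequencies are in cycles per block (cpb) and must be positive integers:
#' every adaptation block contains a whole number of stimulus cycles, so the
#' stimulus gain averages to zero over the block and closes at phase zero.
#'
#' @param block_lengths Integer vector, trials per block (in session order).
#' @param block_types Character vector, `"non-adaptation"` or `"adaptation"`
#'   per block.
#' @param frequencies Integer vector of cycles per block, one entry per
#'   adaptation block (in order). Non-adaptation blocks carry no frequency.
#' @param P Sinusoid amplitude of the ISS in degrees of visual angle (dva).
#' @param preTP Pre-saccadic target amplitude in dva (held constant).
#' @param adaptation_type Label, `"two-way"` or `"global"`.
#' @param constant Constant ISS component in dva (0 in the sinusoidal
#'   paradigm; accepted for generality).
#'
#' @return An object of class `sa_design`: a list with the validated fields
#'   plus the derived ratio `p = P/preTP`.
#' @examples
#' d <- session_design(c(75, 384), c("non-adaptation", "adaptation"), 6)
#' d$p
#' @export
session_design <- function(block_lengths, block_types, frequencies,
                           P = 2, preTP = 8,
                           adaptation_type = c("two-way", "global"),
                           constant = 0) {
  adaptation_type <- match.arg(adaptation_type)
  block_types <- match.arg(block_types,
                           c("non-adaptation", "adaptation"),
                           several.ok = TRUE)
  if (length(block_types) != length(block_lengths)) {
    stop("`block_lengths` and `block_types` must have the same length.",
         call. = FALSE)
  }
  if (any(block_lengths <= 0) || any(block_lengths != round(block_lengths))) {
    stop("All block lengths must be positive integers.", call. = FALSE)
  }
  n_adapt <- sum(block_types == "adaptation")
  if (length(frequencies) != n_adapt) {
    stop("Need exactly one frequency per adaptation block (",
         n_adapt, " needed, ", length(frequencies), " given).",
         call. = FALSE)
  }
  if (any(frequencies <= 0) || any(frequencies != round(frequencies))) {
    stop("Frequencies must be positive integers (whole cycles per block).",
         call. = FALSE)
  }
  if (preTP <= 0) stop("`preTP` must be positive.", call. = FALSE)
  if (P <= 0) stop("`P` must be positive.", call. = FALSE)
  structure(
    list(
      block_lengths = as.integer(block_lengths),
      block_types = block_types,
      frequencies = as.integer(frequencies),
      P = P, preTP = preTP, p = P / preTP,
      constant = constant,
      adaptation_type = adaptation_type
    ),
    class = "sa_design"
  )
}

#' @export
print.sa_design <- function(x, ...) {
  cat("<sa_design> ", x$adaptation_type, " adaptation, ",
      length(x$block_lengths), " blocks, ",
      sum(x$block_lengths), " trials\n", sep = "")
  cat("  P = ", x$P, " dva, preTP = ", x$preTP, " dva, p = ", x$p, "\n",
      sep = "")
  cat("  adaptation blocks: ",
      paste0(x$block_lengths[x$block_types == "adaptation"], " trials @ ",
             x$frequencies, " cpb", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Standard session designs
#'
#' `freq_design()` builds the extended-frequency session: 11 alternating
#' blocks — six non-adaptation blocks of 75 trials interleaved with five
#' adaptation blocks of 384 trials at 1, 3, 6, 12 and 24 cycles per block
#' (2370 trials in total). `orig_design()` builds one single-frequency
#' session of the original design (75 pre-adaptation trials followed by one
#' 384-trial adaptation block), used at 3, 4 and 6 cpb.
#' `single_block_design()` is the same pre + adaptation layout with a free
#' frequency, the unit on which per-condition fits operate.
#'
#' @param frequencies Cycles per block for the adaptation blocks.
#' @param f Cycles per block for the single adaptation block.
#' @param n_pre,n_adapt Trials in the non-adaptation and adaptation blocks.
#' @inheritParams session_design
#' @return An `sa_design`.
#' @examples
#' sum(freq_design()$block_lengths)  # 2370
#' @export
freq_design <- function(frequencies = c(1L, 3L, 6L, 12L, 24L),
                        adaptation_type = "two-way", P = 2, preTP = 8) {
  k <- length(frequencies)
  session_design(
    block_lengths = c(rbind(rep(75L, k), rep(384L, k)), 75L),
    block_types = c(rbind(rep("non-adaptation", k), rep("adaptation", k)),
                    "non-adaptation"),
    frequencies = frequencies,
    P = P, preTP = preTP, adaptation_type = adaptation_type
  )
}

#' @rdname freq_design
#' @export
orig_design <- function(f = 3L, adaptation_type = "two-way",
                        P = 2, preTP = 8) {
  single_block_design(f, adaptation_type = adaptation_type,
                      P = P, preTP = preTP)
}

#' @rdname freq_design
#' @export
single_block_design <- function(f, n_pre = 75L, n_adapt = 384L,
                                adaptation_type = "two-way",
                                P = 2, preTP = 8) {
  session_design(
    block_lengths = c(n_pre, n_adapt),
    block_types = c("non-adaptation", "adaptation"),
    frequencies = f,
    P = P, preTP = preTP, adaptation_type = adaptation_type
  )
}

#' Build the per-trial stimulus series of a session
#'
#' Expands a design into one row per trial. On adaptation trials the
#' stimulus gain is `s = sin(2*pi*f*n_block/N)` with `n_block` the 1-based
#' within-block trial index and `N` the block length: every adaptation block
#' starts at phase zero and completes exactly `f` full cycles. On
#' non-adaptation trials `s = 0`. The target gain is `t = 1 + p*s` and the
#' disturbance gain is `d = p*s`.
#'
#' @param design An [session_design()] object.
#' @return A tibble with columns `trial` (global, 1-based), `block`,
#'   `block_type`, `trial_in_block`, `frequency_cpb` (`NA` in non-adaptation
#'   blocks), `s`, `t`, `d`.
#' @examples
#' trials <- build_session(freq_design())
#' nrow(trials)
#' @export
build_session <- function(design) {
  if (!inherits(design, "sa_design")) {
    stop("`design` must be an `sa_design` (see `session_design()`).",
         call. = FALSE)
  }
  k <- length(design$block_lengths)
  freq_by_block <- rep(NA_integer_, k)
  freq_by_block[design$block_types == "adaptation"] <- design$frequencies
  blocks <- purrr::map(seq_len(k), function(b) {
    N <- design$block_lengths[b]
    n_block <- seq_len(N)
    if (design$block_types[b] == "adaptation") {
      f <- freq_by_block[b]
      s <- sin(2 * pi * f * n_block / N)
    } else {
      s <- rep(0, N)
    }
    tibble::tibble(
      block = b,
      block_type = design$block_types[b],
      trial_in_block = n_block,
      frequency_cpb = freq_by_block[b],
      s = s
    )
  })
  out <- dplyr::bind_rows(blocks)
  out$trial <- seq_len(nrow(out))
  out$t <- target_gain(out$s, design$p)
  out$d <- design$p * out$s
  dplyr::select(out, "trial", "block", "block_type", "trial_in_block",
                "frequency_cpb", "s", "t", "d")
}

#' Target gain from stimulus gain
#'
#' The post- to pre-saccadic target-amplitude ratio: `t = 1 + p*s`, where
#' `p` is the ISS amplitude relative to the pre-saccadic step.
#'
#' @param s Stimulus gain (unit-amplitude sinusoid on adaptation trials).
#' @param p Amplitude ratio `P/preTP` (>= 0).
#' @return Target gain, same length as `s`.
#' @examples
#' target_gain(1, 0.25)  # 1.25
#' @export
target_gain <- function(s, p) {
  if (any(p < 0)) stop("`p` must be non-negative.", call. = FALSE)
  1 + p * s
}

#' Convert between saccade amplitude, saccade gain and adaptation gain
#'
#' The adaptation gain is the residual of the saccade relative to perfect
#' landing, normalized by the ISS sinusoid amplitude:
#' `g = (SA - preTP)/P`. A perfectly accurate saccade (`SA = preTP`) has
#' `g = 0`. `saccade_gain()` is the inverse map on the gain scale,
#' `SG = 1 + (P/preTP)*g`, and `adaptation_gain_from_sg()` inverts it.
#'
#' @param SA Saccade amplitude (dva).
#' @param preTP Pre-saccadic target amplitude (dva), > 0.
#' @param P ISS sinusoid amplitude (dva), > 0 (normalization undefined at 0).
#' @param g Adaptation gain.
#' @param SG Saccade gain.
#' @param p Amplitude ratio `P/preTP`.
#' @return Numeric vector.
#' @examples
#' adaptation_gain(7.5, preTP = 8, P = 2)  # -0.25
#' saccade_gain(-0.25, p = 0.25)
#' @export
adaptation_gain <- function(SA, preTP = 8, P = 2) {
  if (any(preTP <= 0)) stop("`preTP` must be positive.", call. = FALSE)
  if (any(P <= 0)) stop("`P` must be positive (normalization undefined).",
                        call. = FALSE)
  (SA - preTP) / P
}

#' @rdname adaptation_gain
#' @export
saccade_gain <- function(g, p = 0.25) 1 + p * g

#' @rdname adaptation_gain
#' @export
adaptation_gain_from_sg <- function(SG, p = 0.25) (SG - 1) / p

#' Extract one pre-adaptation + adaptation segment from a session
#'
#' Per-condition fits operate on a single adaptation block together with
#' its preceding non-adaptation block (fits include the pre-adaptation
#' trials). Returns the rows of `trials` belonging to the adaptation block
#' with the requested frequency plus the immediately preceding
#' non-adaptation block, with a fresh 1-based `n_fit` index.
#'
#' @param trials A trial tibble from [build_session()] (extra columns such
#'   as `g` are carried along).
#' @param f Frequency (cpb) of the adaptation block to extract.
#' @return A tibble, subset of `trials`, with an added `n_fit` column.
#' @export
session_segment <- function(trials, f) {
  ad_blocks <- unique(trials$block[trials$block_type == "adaptation" &
                                     trials$frequency_cpb == f])
  if (length(ad_blocks) != 1) {
    stop("Expected exactly one adaptation block at f = ", f, " cpb, found ",
         length(ad_blocks), ".", call. = FALSE)
  }
  keep <- trials$block %in% c(ad_blocks - 1L, ad_blocks)
  out <- trials[keep, , drop = FALSE]
  out$n_fit <- seq_len(nrow(out))
  out
}
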