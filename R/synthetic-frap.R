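# Synthetic FRAP traces following the single-exponential recovery model
# I(t) = I0 - a * exp(-beta * t) on the full-scale normalized axis.

#' Generate a synthetic FRAP time series
#'
#' Emits bleached-ROI, reference-ROI and background raw traces whose
#' full-scale normalization recovers the planted single-exponential model
#' `I0 - a * exp(-beta * t)` (bleach at t = 0). Pre-bleach samples sit at
#' the plateau; post-bleach samples follow the model. Raw counts are built
#' from the normalized model by scaling with a reference level and adding a
#' constant background, so the normalization pipeline has real work to do.
#'
#' @param I0 mobile fraction (plateau of the normalized recovery), in [0, 1].
#' @param a recovery amplitude (>= 0); the first post-bleach value is I0 - a.
#' @param beta recovery rate in 1/s (> 0).
#' @param t_grid time grid in seconds; must contain points both below and at
#'   or above 0 (bleach at t = 0).
#' @param noise_sd Gaussian noise SD on the normalized scale (>= 0).
#' @param seed RNG seed or `NULL`.
#' @param reference_level mean reference-ROI counts.
#' @param background_level constant background counts.
#' @param normalized if `TRUE`, bypass the raw-count construction and return
#'   the already-normalized trace in the `bleached` column (generator bypass
#'   mode used to test normalization round-trips).
#' @return data.frame of class `frap_trace` with columns `t_s`, `bleached`,
#'   `reference`, `background`, plus attributes `I0`, `a`, `beta`.
#' @export
generate_frap_trace <- function(I0, a, beta, t_grid,
                                noise_sd = 0, seed = NULL,
                                reference_level = 1000,
                                background_level = 50,
                                normalized = FALSE) {
  if (length(t_grid) == 0L) stopf("t_grid must be non-empty")
  if (I0 < 0 || I0 > 1) stopf("I0 must lie in [0, 1]")
  if (a < 0) stopf("a must be non-negative")
  if (beta <= 0) stopf("beta must be positive")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  t_grid <- sort(t_grid)
  post <- t_grid >= 0
  model <- ifelse(post, I0 - a * exp(-beta * t_grid), 1)
  y <- with_seed(seed, model + if (noise_sd > 0)
    stats::rnorm(length(model), 0, noise_sd) else 0)
  if (normalized) {
    out <- data.frame(t_s = t_grid, bleached = y,
                      reference = rep(1, length(t_grid)),
                      background = rep(0, length(t_grid)))
  } else {
    # raw counts: bleached ROI scaled to reference level, plus background;
    # reference ROI mildly photobleached over time to exercise the
    # double-normalization step
    ref <- reference_level * exp(-1e-4 * pmax(t_grid - min(t_grid), 0))
    out <- data.frame(
      t_s = t_grid,
      bleached = y * ref + background_level,
      reference = ref + background_level,
      background = rep(background_level, length(t_grid))
    )
  }
  attr(out, "I0") <- I0
  attr(out, "a") <- a
  attr(out, "beta") <- beta
  class(out) <- c("frap_trace", "data.frame")
  out
}
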