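# FRAP normalization and single-exponential mobile-fraction fitting.
#
# Normalization follows the double-normalization-plus-full-scale scheme of
# the easyFRAP protocol: background-subtract all traces, divide the
# bleached-ROI trace by the reference-ROI trace (correcting acquisition
# photobleaching), rescale both to their pre-bleach means, then map the
# first post-bleach point to 0 and the pre-bleach plateau to 1. The mobile
# fraction is the plateau I0 of the model I(t) = I0 - a * exp(-beta * t)
# fitted to the post-bleach points.

#' Full-scale normalization of a FRAP trace
#'
#' @param trace data.frame with columns `t_s`, `bleached`, `reference`,
#'   `background` (bleach at t = 0; pre-bleach points have t < 0).
#' @return data.frame with columns `t_s`, `normalized` (full-scale axis),
#'   restricted to all time points; attribute `pre_bleach_mean` records the
#'   double-normalized plateau before rescaling.
#' @export
normalize_fullscale <- function(trace) {
  need <- c("t_s", "bleached", "reference", "background")
  if (!all(need %in% names(trace))) stopf("trace must have columns %s",
                                          paste(need, collapse = ", "))
  t <- trace$t_s
  if (is.unsorted(t, strictly = TRUE)) stopf("t_s must be strictly increasing")
  pre <- t < 0
  if (!any(pre)) stopf("no pre-bleach points (t < 0): cannot normalize")
  bl <- trace$bleached - trace$background
  ref <- trace$reference - trace$background
  if (any(ref <= 0)) stopf("non-positive reference after background subtraction")
  # double normalization: correct for acquisition bleaching, scale both
  # traces to their pre-bleach means
  dn <- (bl / mean(bl[pre])) / (ref / mean(ref[pre]))
  # full-scale: first post-bleach point -> 0, pre-bleach plateau -> 1
  first_post <- which(!pre)[1]
  if (is.na(first_post)) stopf("no post-bleach points")
  plateau <- mean(dn[pre])
  y0 <- dn[first_post]
  if (abs(plateau - y0) < .Machine$double.eps^0.5)
    stopf("no bleach depth: plateau equals first post-bleach value")
  out <- data.frame(t_s = t, normalized = (dn - y0) / (plateau - y0))
  attr(out, "pre_bleach_mean") <- plateau
  out
}

#' Fit the single-exponential recovery model
#'
#' Nonlinear least squares of `I0 - a * exp(-beta * t)` on the post-bleach
#' points of a normalized trace. Initialization: I0 from the last-decile
#' mean, a from I0 minus the first post-bleach value, beta from the time to
#' half recovery; bounds 0 <= I0 <= 1.2, a >= 0, beta > 0. Falls back to a
#' direct least-squares minimization when `nls` declines to converge (as it
#' does on zero-residual data). A flat trace (no recovery) leaves beta
#' unidentifiable and is flagged.
#'
#' @param t time in seconds (post-bleach points, t >= 0, are used).
#' @param y normalized intensity (same length).
#' @return object of class `frap_fit`: list with `I0`, `a`, `beta`,
#'   `cov` (3x3 covariance of the estimates), `se`, `flat` flag,
#'   `at_bounds` flag, `n`.
#' @export
fit_recovery <- function(t, y) {
  post <- t >= 0
  t <- t[post]; y <- y[post]
  if (length(t) < 5L) stopf("need at least 5 post-bleach points")
  lower <- c(I0 = 0, a = 0, beta = 1e-8)
  upper <- c(I0 = 1.2, a = Inf, beta = Inf)
  # deterministic initialization
  dec <- t >= stats::quantile(t, 0.9)
  I0_0 <- mean(y[dec])
  a_0 <- max(I0_0 - y[1], 1e-6)
  half <- y[1] + (I0_0 - y[1]) / 2
  i_half <- which(y >= half)[1]
  beta_0 <- if (!is.na(i_half) && t[i_half] > 0) log(2) / t[i_half] else
    1 / max(t[length(t)], 1)
  span <- max(y) - min(y)
  if (span < 1e-8 || stats::sd(y) < 1e-8 * max(abs(y), 1)) {
    # degenerate flat trace: plateau defined, rate not
    return(structure(list(I0 = mean(y), a = 0, beta = NA_real_,
                          cov = matrix(NA_real_, 3, 3), se = rep(NA_real_, 3),
                          flat = TRUE, at_bounds = FALSE, n = length(t)),
                     class = "frap_fit"))
  }
  start <- list(I0 = min(max(I0_0, 0), 1.2), a = a_0, beta = beta_0)
  dat <- data.frame(t = t, y = y)
  fit <- tryCatch(
    stats::nls(y ~ I0 - a * exp(-beta * t), data = dat, start = start,
               lower = lower, upper = upper, algorithm = "port",
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    est <- stats::coef(fit)
  } else {
    # fall back to bounded quasi-Newton least squares
    obj <- function(p) sum((y - (p[1] - p[2] * exp(-p[3] * t)))^2)
    op <- stats::optim(unlist(start), obj, method = "L-BFGS-B",
                       lower = lower, upper = c(1.2, 1e6, 1e6))
    est <- op$par
    names(est) <- c("I0", "a", "beta")
  }
  I0 <- est[["I0"]]; a <- est[["a"]]; beta <- est[["beta"]]
  # covariance from the analytic Jacobian
  J <- cbind(1, -exp(-beta * t), a * t * exp(-beta * t))
  resid <- y - (I0 - a * exp(-beta * t))
  dof <- max(length(t) - 3L, 1L)
  sigma2 <- sum(resid^2) / dof
  JtJ <- crossprod(J)
  cov <- tryCatch(sigma2 * solve(JtJ), error = function(e) matrix(NA_real_, 3, 3))
  at_bounds <- beta <= lower[["beta"]] * 10 || I0 >= 1.2 - 1e-9
  structure(list(I0 = I0, a = a, beta = beta, cov = cov,
                 se = sqrt(pmax(diag(cov), 0)), flat = FALSE,
                 at_bounds = at_bounds, n = length(t)),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> I0 = %.4f, a = %.4f, beta = %s 1/s%s\n",
              x$I0, x$a, ifelse(is.na(x$beta), "NA", sprintf("%.4g", x$beta)),
              if (x$flat) " [flat trace: beta unidentifiable]" else ""))
  invisible(x)
}

#' Compare mobile fractions between two groups of fits
#'
#' Boxplot summary and two-tailed test of the fitted mobile fractions I0
#' (delegates to [summarize_groups()]).
#'
#' @param fits_a,fits_b lists of `frap_fit` objects (>= 3 each).
#' @param labels group labels, length 2.
#' @return as [summarize_groups()].
#' @export
mobile_fraction_compare <- function(fits_a, fits_b,
                                    labels = c("A", "B")) {
  if (length(fits_a) < 3L || length(fits_b) < 3L)
    stopf("need at least 3 fits per group")
  i0 <- c(vapply(fits_a, `[[`, numeric(1), "I0"),
          vapply(fits_b, `[[`, numeric(1), "I0"))
  grp <- rep(labels, c(length(fits_a), length(fits_b)))
  summarize_groups(i0, grp)
}
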