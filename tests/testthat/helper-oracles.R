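# Independent oracle implementations used to cross-check the package's
# fitting and summary routines. These deliberately avoid the code paths
# they verify: linear fits via explicit normal equations, quantiles via
# sorting, sphere scattering via the closed-form form factor.

# Least squares through normal equations: X^T X b = X^T y.
oracle_lm <- function(X, y) {
  X <- cbind(1, X)
  unname(solve(crossprod(X), crossprod(X, y))[, 1])
}

# Type-7 quantile by direct sort-and-interpolate.
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Solid-sphere form factor P(qR).
sphere_form_factor <- function(q, R) {
  x <- q * R
  (3 * (sin(x) - x * cos(x)) / x^3)^2
}

# Moments of a two-component exponential mixture: brute-force expansion of
# ln g1 around tau = 0 for g1 = w1 exp(-G1 t) + w2 exp(-G2 t).
oracle_bimodal_cumulants <- function(w1, G1, w2, G2) {
  m1 <- w1 * G1 + w2 * G2                       # mean decay rate
  m2 <- w1 * G1^2 + w2 * G2^2
  list(gamma_mean = m1, k2 = (m2 - m1^2) / 2)   # ln g1 = -m1 t + (mu2/2) t^2
}

# Standard 8-detector q grid (1/nm).
standard_q <- function() momentum_transfer(seq(30, 86, by = 8))

# Small calibration record shared across tests (synthetic toluene RR).
test_calib <- function(...) ls_calibration(rr_std = 1.35e-5, ...)
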