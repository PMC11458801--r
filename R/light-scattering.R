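# Time-resolved multi-angle SLS/DLS evaluation: momentum transfer, excess
# Rayleigh ratios, Zimm and Guinier fits, cumulant analysis, z-averaged
# diffusion, Stokes-Einstein hydrodynamic radius, rho = Rg/Rh, and
# induction-time detection over a frame series.

#' Momentum transfer vector
#'
#' `q = 4 pi n / lambda0 * sin(theta / 2)` in 1/nm for scattering angle
#' `theta` in degrees, solvent refractive index `n` and vacuum laser
#' wavelength `lambda0` in nm. With n = 1.332 and lambda0 = 632.8 nm the
#' standard 8-detector range 30--86 degrees maps to
#' 6.8e-3 <= q <= 1.8e-2 1/nm.
#'
#' @param theta scattering angle(s) in degrees, 0 <= theta < 180.
#' @param n solvent refractive index.
#' @param lambda0 laser wavelength in vacuum, nm.
#' @return q in 1/nm.
#' @export
momentum_transfer <- function(theta, n = 1.332, lambda0 = 632.8) {
  if (any(theta < 0 | theta >= 180)) stopf("theta must lie in [0, 180)")
  4 * pi * n / lambda0 * sin(theta * pi / 360)
}

#' Excess Rayleigh ratio from raw multi-angle intensities
#'
#' `dR_theta = RR_std * (r_sol - r_solv) / r_std` per angle, referencing
#' the toluene standard. Angles where the solvent scatters more than the
#' solution (negative excess) are flagged for exclusion from fits.
#'
#' @param frame list with `r_sol`, `r_solv`, `r_std` vectors (one entry per
#'   angle) as produced by [generate_scattering_series()] or read from CSV.
#' @param calib an [ls_calibration()].
#' @return data.frame with columns `angle_deg` (if present in the frame),
#'   `dR` (1/cm) and `usable` (logical).
#' @export
excess_rayleigh <- function(frame, calib) {
  if (any(frame$r_std <= 0)) stopf("standard intensity must be positive at every angle")
  dR <- calib$rr_std * (frame$r_sol - frame$r_solv) / frame$r_std
  usable <- dR > 0
  if (!all(usable))
    warnf("%d angle(s) with non-positive excess scattering excluded", sum(!usable))
  data.frame(angle_deg = frame$angles %||% seq_along(dR), dR = dR,
             usable = usable)
}

#' Optical contrast factor
#'
#' `K = 4 pi^2 n0^2 (dn/dc)^2 / (N_A lambda^4)` in cm^2 mol / g^2, with
#' `n0` the bath refractive index, `dn/dc` in ml/g and `lambda` converted
#' from nm to cm. With concentration in g/ml and dR in 1/cm, `K c / dR` is
#' then mol/g, so Zimm/Guinier intercepts are 1/Mw in mol/g directly.
#'
#' @param calib an [ls_calibration()].
#' @return K in cm^2 mol / g^2.
#' @export
contrast_factor <- function(calib) {
  lambda_cm <- calib$lambda0 * 1e-7
  4 * pi^2 * calib$n0^2 * calib$dndc^2 / (.NA * lambda_cm^4)
}

#' Zimm fit of static scattering data
#'
#' Linear regression of `K c / dR` on `q^2` (and, when several
#' concentrations are supplied, on `c`): intercept is 1/Mw, the q^2 slope
#' is Rg^2 / (3 Mw), and the c slope is 2 A2. At a single concentration the
#' `2 A2 c` term cannot be separated from the intercept and is dropped with
#' a flag, matching time-resolved practice.
#'
#' @param q momentum transfer per observation, 1/nm.
#' @param dR excess Rayleigh ratio per observation, 1/cm.
#' @param K contrast factor from [contrast_factor()].
#' @param conc concentration per observation in g/l (scalar or vector).
#' @return list with `Mw` (g/mol), `Rg` (nm), `A2` (ml mol / g^2 or NA),
#'   `a2_dropped`, `rg_floored` flags.
#' @export
zimm_fit <- function(q, dR, K, conc) {
  keep <- is.finite(dR) & dR > 0
  if (sum(keep) < 3L) stopf("need at least 3 usable angles for a Zimm fit")
  q <- q[keep]; dR <- dR[keep]
  conc_ml <- conc / 1000                       # g/l -> g/ml
  if (length(conc_ml) == 1L) conc_ml <- rep(conc_ml, length(q))
  else conc_ml <- conc_ml[keep]
  y <- K * conc_ml / dR
  multi_c <- length(unique(conc_ml)) > 1L
  if (multi_c) {
    fit <- stats::lm(y ~ I(q^2) + conc_ml)
    co <- stats::coef(fit)
    Mw <- 1 / co[[1]]
    A2 <- co[["conc_ml"]] / 2
    a2_dropped <- FALSE
  } else {
    fit <- stats::lm(y ~ I(q^2))
    co <- stats::coef(fit)
    Mw <- 1 / co[[1]]
    A2 <- NA_real_
    a2_dropped <- TRUE
  }
  rg2 <- 3 * Mw * co[[2]]
  rg_floored <- rg2 < 0
  list(Mw = Mw, Rg = if (rg_floored) 0 else sqrt(rg2), A2 = A2,
       a2_dropped = a2_dropped, rg_floored = rg_floored)
}

#' Guinier fit of static scattering data
#'
#' Guinier approximation: `dR(q) = K c Mw exp(-q^2 Rg^2 / 3)`, fitted as a
#' linear regression of `ln(K c / dR)` on `q^2` whose intercept is
#' `ln(1/Mw)` and whose slope is `+Rg^2/3` (the reciprocal form flips the
#' exponent's sign, consistent with the small-q Zimm expansion
#' `K c / dR = (1/Mw)(1 + Rg^2 q^2/3)`).
#' Angles with non-positive `K c / dR` are dropped; a
#' warning is raised when the fitted size leaves the Guinier regime
#' (`q * Rg > 1.3` at the largest usable angle).
#'
#' @inheritParams zimm_fit
#' @param conc concentration in g/l (single value).
#' @return list with `Mw` (g/mol), `Rg` (nm), `rg_floored`, `qrg_max`.
#' @export
guinier_fit <- function(q, dR, K, conc) {
  conc_ml <- conc / 1000
  y_raw <- K * conc_ml / dR
  keep <- is.finite(y_raw) & y_raw > 0
  if (sum(keep) < 3L) stopf("fewer than 3 usable angles for a Guinier fit")
  q <- q[keep]
  y <- log(y_raw[keep])
  fit <- stats::lm(y ~ I(q^2))
  co <- stats::coef(fit)
  Mw <- exp(-co[[1]])
  rg2 <- 3 * co[[2]]
  rg_floored <- rg2 < 0
  Rg <- if (rg_floored) 0 else sqrt(rg2)
  qrg_max <- max(q) * Rg
  if (qrg_max > 1.3)
    warnf("q*Rg = %.2f at the largest angle: outside the Guinier regime", qrg_max)
  list(Mw = Mw, Rg = Rg, rg_floored = rg_floored, qrg_max = qrg_max)
}

#' Second-order cumulant fit of a field correlation function
#'
#' Quadratic fit of `ln g1(tau) = A - q^2 D tau + q^4 k2 tau^2` over the
#' lag window where `g1 > 0.1 * g1(0)` (later lags are noise-dominated).
#'
#' @param g1 field correlation values at one angle.
#' @param tau lag times in seconds, strictly increasing.
#' @param q momentum transfer at this angle, 1/m.
#' @return list with `D` (m^2/s), `k2` (second cumulant, m^4 s^-2 scaled),
#'   `A` (intercept, log scale), `n_used`.
#' @export
cumulant_fit <- function(g1, tau, q) {
  if (length(g1) != length(tau)) stopf("g1 and tau lengths differ")
  window <- g1 > 0.1 * g1[1] & g1 > 0
  if (sum(window) < 4L) stopf("correlation function does not decay cleanly (too few usable lags)")
  tt <- tau[window]
  y <- log(g1[window])
  fit <- stats::lm(y ~ tt + I(tt^2))
  co <- stats::coef(fit)
  D <- -co[[2]] / q^2
  if (D <= 0) stopf("non-decaying correlation function: fitted D <= 0")
  list(D = D, k2 = co[[3]] / q^4, A = co[[1]], n_used = sum(window))
}

#' Extrapolate apparent diffusion coefficients to zero angle
#'
#' Linear regression of the per-angle apparent `D` on `q^2`:
#' `D = Dz (1 + q^2 Rg^2 C)` (the concentration term `k_d c` is neglected
#' in time-resolved work). Intercept is the z-averaged `Dz`; when `Rg` is
#' supplied the slope is converted to the angular-dependence coefficient
#' `C`. With fewer than 3 valid angles the mean D is returned with a flag.
#'
#' @param D apparent diffusion coefficients per angle, m^2/s.
#' @param q momentum transfer per angle, 1/nm or 1/m (consistent with the
#'   desired C units; Rg must use the inverse length unit of q).
#' @param Rg radius of gyration (same length unit as 1/q) or `NA`.
#' @return list with `Dz`, `C_slope` (raw slope), `C` (dimensionless, or NA),
#'   `fallback` flag.
#' @export
extrapolate_Dz <- function(D, q, Rg = NA_real_) {
  keep <- is.finite(D)
  if (sum(keep) < 3L) {
    return(list(Dz = mean(D[keep]), C_slope = NA_real_, C = NA_real_,
                fallback = TRUE))
  }
  fit <- stats::lm(D[keep] ~ I(q[keep]^2))
  co <- stats::coef(fit)
  Dz <- co[[1]]
  C <- if (is.finite(Rg) && Rg > 0 && Dz > 0) co[[2]] / (Dz * Rg^2) else NA_real_
  list(Dz = Dz, C_slope = co[[2]], C = C, fallback = FALSE)
}

#' Hydrodynamic radius via Stokes-Einstein
#'
#' `Rh = kB T / (6 pi eta Dz)`, returned in nm.
#'
#' @param Dz z-averaged diffusion coefficient, m^2/s (> 0).
#' @param calib an [ls_calibration()] providing `eta` (mPa s) and
#'   `temperature` (K).
#' @return Rh in nm.
#' @export
stokes_einstein <- function(Dz, calib) {
  if (any(Dz <= 0)) stopf("Dz must be positive")
  .kB * calib$temperature / (6 * pi * calib$eta * 1e-3 * Dz) * 1e9
}

#' Structure-sensitive size ratio
#'
#' `rho = Rg / Rh`; approximately 0.775 for homogeneous spheres, larger for
#' elongated or coil-like particles.
#'
#' @param Rg radius of gyration, nm.
#' @param Rh hydrodynamic radius, nm (> 0).
#' @return dimensionless ratio.
#' @export
rho_ratio <- function(Rg, Rh) {
  if (any(Rh <= 0)) stopf("Rh must be positive")
  Rg / Rh
}

#' Analyse a time-resolved scattering series
#'
#' Runs the full evaluation chain per frame: excess Rayleigh ratios,
#' Guinier fit (Mw, Rg), per-angle cumulant fits, zero-angle extrapolation
#' (Dz), Stokes-Einstein (Rh) and rho = Rg/Rh. The induction time is the
#' time of the first frame at which Mw exceeds the baseline mean plus
#' 3 baseline standard deviations for 3 consecutive frames; baseline frames
#' are those with `t <= 0` (pre-addition).
#'
#' @param series a `scattering_series` (from [generate_scattering_series()]
#'   or [read_scattering_frames()]).
#' @param calib an [ls_calibration()]; defaults to the series' own.
#' @return list of class `ls_result_series`: `results` data.frame with
#'   columns `t_s`, `Mw_g_mol`, `Rg_nm`, `Dz_m2_s`, `Rh_nm`, `rho`, and
#'   `induction_time_s` (NA if never detected), `baseline_Mw`,
#'   `baseline_sd`.
#' @export
analyze_series <- function(series, calib = NULL) {
  calib <- calib %||% series$calib
  if (is.null(calib)) stopf("no calibration supplied")
  frames <- series$frames
  if (length(frames) == 0L) stopf("empty frame list")
  K <- contrast_factor(calib)
  res <- data.frame(t_s = numeric(0), Mw_g_mol = numeric(0), Rg_nm = numeric(0),
                    Dz_m2_s = numeric(0), Rh_nm = numeric(0), rho = numeric(0))
  for (fr in frames) {
    q <- momentum_transfer(fr$angles, calib$n, calib$lambda0)  # 1/nm
    er <- suppressWarnings(excess_rayleigh(fr, calib))
    gf <- suppressWarnings(
      guinier_fit(q[er$usable], er$dR[er$usable], K, calib$concentration))
    q_m <- q * 1e9
    D <- vapply(seq_along(q), function(j) {
      tryCatch(cumulant_fit(fr$g1[j, ], fr$tau, q_m[j])$D,
               error = function(e) NA_real_)
    }, numeric(1))
    ex <- extrapolate_Dz(D, q_m, Rg = gf$Rg * 1e-9)
    Rh <- stokes_einstein(ex$Dz, calib)
    res <- rbind(res, data.frame(
      t_s = fr$t, Mw_g_mol = gf$Mw, Rg_nm = gf$Rg, Dz_m2_s = ex$Dz,
      Rh_nm = Rh, rho = rho_ratio(gf$Rg, Rh)))
  }
  base <- res$t_s <= 0
  if (!any(base)) {
    warnf("no baseline frames (t <= 0): induction time undefined")
    induction <- NA_real_
    base_mean <- NA_real_; base_sd <- NA_real_
  } else {
    base_mean <- mean(res$Mw_g_mol[base])
    base_sd <- stats::sd(res$Mw_g_mol[base])
    if (is.na(base_sd)) base_sd <- 0
    thr <- base_mean + 3 * base_sd
    above <- res$Mw_g_mol > thr & !base
    induction <- NA_real_
    runlen <- 0L
    for (i in seq_along(above)) {
      runlen <- if (above[i]) runlen + 1L else 0L
      if (runlen == 3L) { induction <- res$t_s[i - 2L]; break }
    }
  }
  structure(
    list(results = res, induction_time_s = induction,
         baseline_Mw = base_mean, baseline_sd = base_sd),
    class = "ls_result_series"
  )
}
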