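# Synthetic time-resolved multi-angle SLS/DLS series for droplet
# nucleation-and-growth, with ground truth attached.

#' Light-scattering calibration record
#'
#' Optical and physical constants needed to turn raw multi-angle
#' intensities into absolute excess Rayleigh ratios and diffusion
#' coefficients into hydrodynamic radii. Defaults are the constants of a
#' He-Ne goniometer with a toluene index bath and aqueous solvent:
#' n0 = 1.496 (toluene), n = 1.332 (water), lambda0 = 632.8 nm,
#' dn/dc = 0.187 ml/g (proteins in water), eta = 0.891 mPa s, T = 298.15 K.
#' The absolute Rayleigh ratio of toluene `rr_std` has no default and must
#' be supplied (instrument-specific calibration).
#'
#' @param rr_std absolute Rayleigh ratio of the toluene standard in 1/cm.
#' @param n0 refractive index of the goniometer bath liquid.
#' @param n refractive index of the solvent.
#' @param lambda0 laser wavelength in vacuum, nm.
#' @param dndc refractive index increment in ml/g.
#' @param eta dynamic viscosity of the solvent in mPa s.
#' @param temperature temperature in Kelvin.
#' @param concentration solute mass concentration in g/l.
#' @return object of class `ls_calibration`.
#' @export
ls_calibration <- function(rr_std, n0 = 1.496, n = 1.332, lambda0 = 632.8,
                           dndc = 0.187, eta = 0.891, temperature = 298.15,
                           concentration = 8e-3) {
  vals <- c(rr_std = rr_std, n0 = n0, n = n, lambda0 = lambda0, dndc = dndc,
            eta = eta, temperature = temperature, concentration = concentration)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stopf("all calibration constants must be finite and strictly positive")
  structure(as.list(vals), class = "ls_calibration")
}

#' Droplet nucleation-and-growth model
#'
#' Ground-truth model for the synthetic scattering series: before
#' `nucleation_time` only the baseline solute (molar mass `baseline_Mw`)
#' scatters; afterwards spherical droplets appear at constant number
#' density and their radius grows as
#' `radius_max * (1 - exp(-(t - nucleation_time) / tau_growth))`.
#' Droplet polydispersity is a lognormal radius distribution with relative
#' standard deviation `polydispersity`.
#'
#' @param nucleation_time seconds (after solute addition at t = 0).
#' @param radius_max asymptotic droplet radius, nm.
#' @param tau_growth growth time constant, s.
#' @param number_density droplets per ml (sets how much solute mass ends up
#'   in droplets).
#' @param polydispersity relative SD of the droplet radius (>= 0).
#' @param baseline_Mw weight-averaged molar mass of the pre-nucleation
#'   solute, g/mol.
#' @param droplet_density effective droplet mass density, g/ml (dilute
#'   protein condensate).
#' @return object of class `droplet_growth_model`.
#' @export
droplet_growth_model <- function(nucleation_time = 300,
                                 radius_max = 150,
                                 tau_growth = 100,
                                 number_density = 1.5e9,
                                 polydispersity = 0.1,
                                 baseline_Mw = 1.5e5,
                                 droplet_density = 0.4) {
  if (polydispersity < 0) stopf("polydispersity must be non-negative")
  if (baseline_Mw <= 0) stopf("baseline_Mw must be positive")
  structure(
    list(nucleation_time = nucleation_time, radius_max = radius_max,
         tau_growth = tau_growth, number_density = number_density,
         polydispersity = polydispersity, baseline_Mw = baseline_Mw,
         droplet_density = droplet_density),
    class = "droplet_growth_model"
  )
}

# Mean droplet radius (nm) at time t; 0 before nucleation.
model_radius <- function(model, t) {
  ifelse(t < model$nucleation_time, 0,
         model$radius_max * (1 - exp(-(t - model$nucleation_time) /
                                       model$tau_growth)))
}

# Lognormal radius quadrature: nodes and number weights approximating a
# lognormal with mean `mean_r` and relative SD `pd`.
radius_nodes <- function(mean_r, pd, n_nodes = 15L) {
  if (pd <= 0 || mean_r <= 0) return(list(r = mean_r, w = 1))
  sdlog <- sqrt(log(1 + pd^2))
  meanlog <- log(mean_r) - sdlog^2 / 2
  p <- (seq_len(n_nodes) - 0.5) / n_nodes
  list(r = stats::qlnorm(p, meanlog, sdlog), w = rep(1 / n_nodes, n_nodes))
}

# Physical constants
.kB <- 1.380649e-23       # J/K
.NA <- 6.02214076e23      # 1/mol

# Molar mass (g/mol) of a spherical droplet of radius r (nm) and density
# rho (g/ml = g/cm^3): M = (4/3) pi r^3 rho N_A with r in cm.
sphere_molar_mass <- function(r_nm, rho) {
  (4 / 3) * pi * (r_nm * 1e-7)^3 * rho * .NA
}

# Stokes-Einstein diffusion coefficient (m^2/s) of a sphere of radius r_nm
# in a solvent of viscosity eta_mPas at temperature T_K.
sphere_diffusion <- function(r_nm, eta_mPas, T_K) {
  .kB * T_K / (6 * pi * eta_mPas * 1e-3 * r_nm * 1e-9)
}

#' Generate a time-resolved multi-angle scattering series
#'
#' Builds per-frame SLS intensities and DLS field correlation functions for
#' a [droplet_growth_model()] observed with the standard 8-detector
#' geometry (30--86 degrees in 8-degree increments). SLS intensities are
#' consistent with Guinier scattering of the instantaneous (lognormal) size
#' distribution: the excess Rayleigh ratio at angle theta is
#' `K * sum_i c_i M_i exp(-q^2 Rg_i^2 / 3)` over baseline solute and
#' droplet size classes, inverted to raw solution/solvent/standard counts
#' through the toluene standard. The field correlation function at each
#' angle is the intensity-weighted mixture `sum_i I_i exp(-q^2 D_i tau)`
#' with `D_i` from Stokes-Einstein, so a monodisperse model yields a single
#' exponential by construction.
#'
#' @param model a [droplet_growth_model()].
#' @param calib an [ls_calibration()].
#' @param frame_interval seconds per time frame (default 10).
#' @param n_frames number of frames after solute addition (t = 0).
#' @param n_baseline number of pre-addition baseline frames (negative t).
#' @param noise relative Gaussian noise on raw intensities and absolute
#'   noise on g1 (a single relative scale; 0 disables noise).
#' @param seed RNG seed or `NULL`.
#' @param tau lag-time grid for g1, seconds.
#' @param angles detector angles in degrees.
#' @return list of class `scattering_series`: `frames` (list of per-frame
#'   lists with `t`, `angles`, `r_sol`, `r_solv`, `r_std`, `g1` matrix
#'   [angle x tau], `tau`), `calib`, and ground `truth` (model plus per-frame
#'   radius). A warning is issued if q*Rg leaves the Guinier regime
#'   (q*Rg > 2 at all angles).
#' @export
generate_scattering_series <- function(model, calib,
                                       frame_interval = 10,
                                       n_frames = 120L,
                                       n_baseline = 12L,
                                       noise = 0,
                                       seed = NULL,
                                       tau = 10^seq(-5, 0, length.out = 60),
                                       angles = seq(30, 86, by = 8)) {
  stopifnot(inherits(model, "droplet_growth_model"),
            inherits(calib, "ls_calibration"))
  if (length(angles) != 8L || any(diff(angles) != 8))
    warnf("non-standard detector geometry: expected 8 angles at 8 degree increments")
  t_frames <- c(-(rev(seq_len(n_baseline))) * frame_interval,
                (seq_len(n_frames) - 1L) * frame_interval)
  q <- momentum_transfer(angles, calib$n, calib$lambda0)   # 1/nm
  K <- contrast_factor(calib)                               # cm^2 mol / g^2
  c_total <- calib$concentration / 1000                     # g/ml
  r_solv <- 0.1; r_std <- 1.0                               # arbitrary counts

  max_r <- model_radius(model, max(t_frames))
  if (max_r > 0 && min(q) * sqrt(3 / 5) * max_r > 2)
    warnf("q*Rg > 2 at all angles: Guinier regime violated for late frames")

  with_seed(seed, {
    frames <- vector("list", length(t_frames))
    truth_radius <- numeric(length(t_frames))
    for (k in seq_along(t_frames)) {
      t_k <- t_frames[k]
      r_mean <- model_radius(model, t_k)
      truth_radius[k] <- r_mean
      if (r_mean > 0) {
        nodes <- radius_nodes(r_mean, model$polydispersity)
        m_i <- sphere_molar_mass(nodes$r, model$droplet_density)
        # droplet mass concentration from number density (per ml)
        c_drop_i <- nodes$w * model$number_density * m_i / .NA   # g/ml
        c_drop <- sum(c_drop_i)
        if (c_drop >= c_total) {  # cap: droplets cannot exceed total solute
          c_drop_i <- c_drop_i * (0.95 * c_total / c_drop)
          c_drop <- sum(c_drop_i)
        }
        c_base <- c_total - c_drop
        conc <- c(c_base, c_drop_i)
        mass <- c(model$baseline_Mw, m_i)
        rg <- c(0, sqrt(3 / 5) * nodes$r)
        dif <- c(sphere_diffusion(2, calib$eta, calib$temperature),
                 sphere_diffusion(nodes$r, calib$eta, calib$temperature))
      } else {
        conc <- c_total
        mass <- model$baseline_Mw
        rg <- 0
        dif <- sphere_diffusion(2, calib$eta, calib$temperature)
      }
      # per-angle excess Rayleigh ratio and g1
      q_m <- q * 1e9                                         # 1/m
      dR <- numeric(length(q))
      g1 <- matrix(0, length(q), length(tau))
      for (j in seq_along(q)) {
        w_int <- conc * mass * exp(-q[j]^2 * rg^2 / 3)       # intensity weights
        dR[j] <- K * sum(w_int)
        g1[j, ] <- as.vector(crossprod(w_int / sum(w_int),
                                       exp(-q_m[j]^2 * outer(dif, tau))))
      }
      r_sol <- r_solv + dR / calib$rr_std * r_std
      if (noise > 0) {
        r_sol <- r_sol * (1 + stats::rnorm(length(r_sol), 0, noise))
        g1 <- g1 + matrix(stats::rnorm(length(g1), 0, noise * 0.02),
                          nrow(g1), ncol(g1))
      }
      frames[[k]] <- list(t = t_k, angles = angles,
                          r_sol = r_sol,
                          r_solv = rep(r_solv, length(angles)),
                          r_std = rep(r_std, length(angles)),
                          tau = tau, g1 = g1)
    }
    structure(
      list(frames = frames, calib = calib,
           truth = list(model = model, t = t_frames, radius = truth_radius)),
      class = "scattering_series"
    )
  })
}
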