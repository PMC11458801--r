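# Synthetic emission spectra and temperature-ramp absorbance spectra.

#' Emission spectrum model for monomeric or J-aggregated dye
#'
#' Gaussian band model. The monomer is a weak broad band spanning roughly
#' 520--650 nm with its maximum near 560 nm; the J-aggregate is an intense
#' narrow band at 575 nm, its width much smaller than the monomer's.
#'
#' @param species `"monomer"` or `"aggregate"`.
#' @param center peak wavelength in nm.
#' @param width Gaussian sigma in nm.
#' @param amplitude peak amplitude in arbitrary units.
#' @param baseline additive baseline in arbitrary units.
#' @return An object of class `spectrum_model`.
#' @export
spectrum_model <- function(species = c("monomer", "aggregate"),
                           center = NULL, width = NULL,
                           amplitude = NULL, baseline = 0) {
  species <- match.arg(species)
  defaults <- switch(species,
    monomer   = list(center = 560, width = 38, amplitude = 1),
    aggregate = list(center = 575, width = 4,  amplitude = 5)
  )
  structure(
    list(species = species,
         center = center %||% defaults$center,
         width = width %||% defaults$width,
         amplitude = amplitude %||% defaults$amplitude,
         baseline = baseline),
    class = "spectrum_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

eval_spectrum_model <- function(model, wavelength) {
  model$baseline + model$amplitude * exp(-(wavelength - model$center)^2 /
                                           (2 * model$width^2))
}

#' Generate a (possibly mixed) emission spectrum
#'
#' Blends the monomer and aggregate band models with weight
#' `mixture_weight` on the aggregate and adds Gaussian noise.
#'
#' @param mixture_weight fraction of aggregate signal in [0, 1]; 0 is pure
#'   monomer, 1 pure aggregate.
#' @param noise_sd additive Gaussian noise SD in arbitrary units (>= 0).
#' @param seed RNG seed or `NULL`.
#' @param monomer,aggregate [spectrum_model()] objects.
#' @param wavelength wavelength grid in nm; must cover 500--700 nm.
#' @return data.frame with columns `wavelength_nm`, `intensity`.
#' @export
generate_emission_spectrum <- function(mixture_weight, noise_sd = 0, seed = NULL,
                                       monomer = spectrum_model("monomer"),
                                       aggregate = spectrum_model("aggregate"),
                                       wavelength = 500:700) {
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  if (mixture_weight < 0 || mixture_weight > 1)
    stopf("mixture_weight must lie in [0, 1]")
  if (min(wavelength) > 500 || max(wavelength) < 700)
    stopf("wavelength grid must cover 500-700 nm")
  pure_m <- eval_spectrum_model(monomer, wavelength)
  pure_a <- eval_spectrum_model(aggregate, wavelength)
  y <- (1 - mixture_weight) * pure_m + mixture_weight * pure_a
  if (noise_sd > 0) {
    y <- with_seed(seed, y + stats::rnorm(length(y), 0, noise_sd))
  }
  data.frame(wavelength_nm = wavelength, intensity = y)
}

#' Generate a temperature-ramp absorbance series
#'
#' Emulates a UV--Vis cooling ramp starting at 25 degrees C in which a
#' sharp 573 nm absorbance peak (the J-aggregate signature) appears only at
#' temperatures strictly below a planted threshold `T_JA_true`. Each
#' spectrum covers 400--600 nm at 1 nm steps: a broad monomer absorption
#' band near 525 nm is always present; below threshold the narrow 573 nm
#' band is added with amplitude `peak_amp(T)`.
#'
#' @param T_JA_true planted threshold temperature in degrees C.
#' @param T_grid strictly descending temperatures in degrees C.
#' @param peak_amp either a single number (constant peak amplitude below
#'   threshold) or a function of temperature returning the amplitude.
#' @param noise_sd additive Gaussian noise SD (absorbance units).
#' @param seed RNG seed or `NULL`.
#' @return An object of class `absorbance_ramp`: list with `temperatures`,
#'   `wavelength`, `spectra` (matrix, one row per temperature),
#'   `T_JA_true`, and `in_grid` (FALSE when the planted threshold lies
#'   outside the ramp, so detection must report a censored result).
#' @export
generate_absorbance_ramp <- function(T_JA_true,
                                     T_grid = seq(25, 20, by = -0.5),
                                     peak_amp = 0.5,
                                     noise_sd = 0.002,
                                     seed = NULL) {
  if (any(diff(T_grid) >= 0)) stopf("T_grid must be strictly descending")
  wavelength <- 400:600
  amp_fun <- if (is.function(peak_amp)) peak_amp else function(T) peak_amp
  with_seed(seed, {
    spectra <- matrix(0, length(T_grid), length(wavelength))
    for (i in seq_along(T_grid)) {
      Ti <- T_grid[i]
      y <- 0.05 + 0.8 * exp(-(wavelength - 525)^2 / (2 * 20^2))
      if (Ti < T_JA_true) {
        y <- y + amp_fun(Ti) * exp(-(wavelength - 573)^2 / (2 * 2.5^2))
      }
      if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
      spectra[i, ] <- pmax(y, 0)
    }
    structure(
      list(temperatures = T_grid, wavelength = wavelength, spectra = spectra,
           T_JA_true = T_JA_true,
           in_grid = T_JA_true > min(T_grid) && T_JA_true <= max(T_grid)),
      class = "absorbance_ramp"
    )
  })
}
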