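# Detection of the J-aggregation threshold temperature T_JA from
# temperature-ramp absorbance spectra: the highest temperature from which
# the sharp 573 nm peak is present in the spectrum and in every spectrum
# measured at lower temperature.

# Prominence of the 573 nm peak in one spectrum: maximum height above a
# linear baseline through the 560 and 590 nm points, within 573 +/- 2 nm.
peak_prominence_573 <- function(wavelength, absorbance) {
  if (!(573 %in% round(wavelength)) && (min(wavelength) > 571 || max(wavelength) < 575))
    stopf("wavelength grid must cover 573 nm")
  y560 <- absorbance[which.min(abs(wavelength - 560))]
  y590 <- absorbance[which.min(abs(wavelength - 590))]
  base_at <- function(x) y560 + (y590 - y560) * (x - 560) / 30
  win <- wavelength >= 571 & wavelength <= 575
  max(absorbance[win] - base_at(wavelength[win]))
}

#' Detect the J-aggregation threshold temperature
#'
#' Scans a cooling ramp (strictly descending temperatures) and returns the
#' highest temperature at which the 573 nm peak prominence exceeds
#' `prominence_floor` and continues to exceed it at every lower measured
#' temperature. The persistence requirement guards against single-spectrum
#' noise blips. When no prominence floor is given it defaults to 5 times
#' the spectral noise SD estimated from first differences over 400--500 nm
#' of the first (warmest) spectrum.
#'
#' @param ramp an `absorbance_ramp` (from [generate_absorbance_ramp()] or
#'   [read_absorbance_ramp()]).
#' @param prominence_floor absorbance units; `NULL` for the default.
#' @return list with `T_JA` (degrees C, `NA` if never reached), `censored`
#'   (`"none"`, `"start"` when the peak is already present at the warmest
#'   temperature, or `"not_reached"`), and `prominence` per temperature.
#' @export
detect_peak_onset <- function(ramp, prominence_floor = NULL) {
  Tg <- ramp$temperatures
  if (any(diff(Tg) >= 0)) stopf("temperatures must be strictly descending")
  prom <- vapply(seq_along(Tg), function(i) {
    peak_prominence_573(ramp$wavelength, ramp$spectra[i, ])
  }, numeric(1))
  if (is.null(prominence_floor)) {
    lo <- ramp$wavelength >= 400 & ramp$wavelength <= 500
    noise <- stats::sd(diff(ramp$spectra[1, lo])) / sqrt(2)
    prominence_floor <- 5 * max(noise, 1e-12)
  }
  sharp <- prom > prominence_floor
  if (!any(sharp)) {
    return(list(T_JA = NA_real_, censored = "not_reached", prominence = prom,
                prominence_floor = prominence_floor))
  }
  # highest temperature from which all lower measurements stay sharp
  persist_from <- which(rev(cumall(rev(sharp))))
  if (length(persist_from) == 0L) {
    return(list(T_JA = NA_real_, censored = "not_reached", prominence = prom,
                prominence_floor = prominence_floor))
  }
  onset <- min(persist_from)
  censored <- if (onset == 1L) "start" else "none"
  list(T_JA = Tg[onset], censored = censored, prominence = prom,
       prominence_floor = prominence_floor)
}

# cumulative AND
cumall <- function(x) cumprod(as.logical(x)) > 0

#' Threshold temperature as a function of condition
#'
#' Runs [detect_peak_onset()] on each ramp and averages replicate T_JA
#' values per condition (e.g. crowder weight percent). All-censored
#' conditions are reported with `NA` mean and flagged.
#'
#' @param ramps list of `absorbance_ramp` objects.
#' @param conditions condition label per ramp.
#' @param ... passed to [detect_peak_onset()].
#' @return data.frame with one row per condition: `condition`, `n_replicates`,
#'   `n_detected`, `T_JA_C` (mean over detected replicates, NA if none),
#'   `censored` (TRUE when no replicate yielded a threshold).
#' @export
threshold_vs_condition <- function(ramps, conditions, ...) {
  stopifnot(length(ramps) == length(conditions))
  det <- lapply(ramps, detect_peak_onset, ...)
  tja <- vapply(det, `[[`, numeric(1), "T_JA")
  out <- do.call(rbind, lapply(split(seq_along(tja), conditions), function(ix) {
    vals <- tja[ix]
    data.frame(condition = conditions[ix[1]],
               n_replicates = length(ix),
               n_detected = sum(!is.na(vals)),
               T_JA_C = if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE),
               censored = all(is.na(vals)))
  }))
  rownames(out) <- NULL
  # preserve the order conditions first appear in
  out[order(match(out$condition, conditions)), , drop = FALSE]
}
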