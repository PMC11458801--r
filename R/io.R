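# Plain-text serialization of pipeline inputs and outputs.
#
# Images are stored as CSV rasters (one file per channel) with a JSON
# sidecar carrying the band metadata; traces, frames and ramps use fixed
# long-format CSV schemas. All writers are deterministic: re-running a
# writer on the same object produces identical bytes.

write_matrix_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
}

read_matrix_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}

#' Write / read a spectral image as CSV rasters plus JSON sidecar
#'
#' @param image a [spectral_image()].
#' @param dir output directory (created if needed).
#' @param stem file stem; channels go to `<stem>_ch<i>.csv`, metadata to
#'   `<stem>_meta.json`.
#' @return invisibly, the metadata path.
#' @export
write_spectral_image <- function(image, dir, stem = "image") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(image$channels)) {
    write_matrix_csv(image$channels[[i]],
                     file.path(dir, sprintf("%s_ch%d.csv", stem, i)))
  }
  meta <- list(
    n_channels = length(image$channels),
    bands = apply(image$bands, 1, function(r) list(lo = r[[1]], hi = r[[2]])),
    bit_depth = image$bit_depth,
    pixel_size_um = image$pixel_size
  )
  mp <- file.path(dir, sprintf("%s_meta.json", stem))
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(mp)
}

#' @rdname write_spectral_image
#' @export
read_spectral_image <- function(dir, stem = "image") {
  meta <- jsonlite::read_json(file.path(dir, sprintf("%s_meta.json", stem)))
  ch <- lapply(seq_len(meta$n_channels), function(i) {
    read_matrix_csv(file.path(dir, sprintf("%s_ch%d.csv", stem, i)))
  })
  bands <- do.call(rbind, lapply(meta$bands, function(b) c(b$lo, b$hi)))
  spectral_image(ch, bands, bit_depth = meta$bit_depth,
                 pixel_size = meta$pixel_size_um %||% NA_real_)
}

#' Write / read a FRAP trace CSV (`t_s, bleached, reference, background`)
#' @param trace a `frap_trace` data.frame.
#' @param path CSV path.
#' @export
write_frap_trace <- function(trace, path) {
  utils::write.csv(trace[c("t_s", "bleached", "reference", "background")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frap_trace
#' @export
read_frap_trace <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t_s", "bleached", "reference", "background")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("FRAP CSV missing column(s): %s", paste(miss, collapse = ", "))
  df
}

#' Write / read scattering frames in long CSV format
#'
#' Two files: `<stem>_sls.csv` (`t_s, angle_deg, r_sol, r_solv, r_std`) and
#' `<stem>_dls.csv` (`t_s, angle_deg, tau_s, g1`); calibration in
#' `<stem>_calibration.json`.
#'
#' @param series a `scattering_series`.
#' @param dir output directory.
#' @param stem file stem.
#' @export
write_scattering_frames <- function(series, dir, stem = "scattering") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sls <- do.call(rbind, lapply(series$frames, function(fr) {
    data.frame(t_s = fr$t, angle_deg = fr$angles, r_sol = fr$r_sol,
               r_solv = fr$r_solv, r_std = fr$r_std)
  }))
  dls <- do.call(rbind, lapply(series$frames, function(fr) {
    do.call(rbind, lapply(seq_along(fr$angles), function(j) {
      data.frame(t_s = fr$t, angle_deg = fr$angles[j], tau_s = fr$tau,
                 g1 = fr$g1[j, ])
    }))
  }))
  utils::write.csv(sls, file.path(dir, paste0(stem, "_sls.csv")), row.names = FALSE)
  utils::write.csv(dls, file.path(dir, paste0(stem, "_dls.csv")), row.names = FALSE)
  jsonlite::write_json(unclass(series$calib),
                       file.path(dir, paste0(stem, "_calibration.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_scattering_frames
#' @export
read_scattering_frames <- function(dir, stem = "scattering") {
  sls <- utils::read.csv(file.path(dir, paste0(stem, "_sls.csv")))
  dls <- utils::read.csv(file.path(dir, paste0(stem, "_dls.csv")))
  for (nm in c("t_s", "angle_deg", "r_sol", "r_solv", "r_std")) {
    if (!nm %in% names(sls)) stopf("SLS CSV missing column %s", nm)
  }
  for (nm in c("t_s", "angle_deg", "tau_s", "g1")) {
    if (!nm %in% names(dls)) stopf("DLS CSV missing column %s", nm)
  }
  calib <- jsonlite::read_json(file.path(dir, paste0(stem, "_calibration.json")))
  calib <- do.call(ls_calibration, calib[c("rr_std", "n0", "n", "lambda0",
                                           "dndc", "eta", "temperature",
                                           "concentration")])
  frames <- lapply(split(sls, sls$t_s), function(sf) {
    t_k <- sf$t_s[1]
    o <- order(sf$angle_deg)
    sf <- sf[o, ]
    df <- dls[dls$t_s == t_k, ]
    tau <- sort(unique(df$tau_s))
    g1 <- t(vapply(sf$angle_deg, function(a) {
      da <- df[df$angle_deg == a, ]
      da$g1[order(da$tau_s)]
    }, numeric(length(tau))))
    list(t = t_k, angles = sf$angle_deg, r_sol = sf$r_sol, r_solv = sf$r_solv,
         r_std = sf$r_std, tau = tau, g1 = g1)
  })
  frames <- frames[order(vapply(frames, `[[`, numeric(1), "t"))]
  names(frames) <- NULL
  structure(list(frames = frames, calib = calib, truth = NULL),
            class = "scattering_series")
}

#' Write / read a temperature-ramp absorbance CSV
#' (`temperature_C, wavelength_nm, absorbance`)
#' @param ramp an `absorbance_ramp`.
#' @param path CSV path.
#' @export
write_absorbance_ramp <- function(ramp, path) {
  df <- do.call(rbind, lapply(seq_along(ramp$temperatures), function(i) {
    data.frame(temperature_C = ramp$temperatures[i],
               wavelength_nm = ramp$wavelength,
               absorbance = ramp$spectra[i, ])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_absorbance_ramp
#' @export
read_absorbance_ramp <- function(path) {
  df <- utils::read.csv(path)
  for (nm in c("temperature_C", "wavelength_nm", "absorbance")) {
    if (!nm %in% names(df)) stopf("ramp CSV missing column %s", nm)
  }
  temps <- unique(df$temperature_C)
  wl <- sort(unique(df$wavelength_nm))
  spectra <- t(vapply(temps, function(Ti) {
    d <- df[df$temperature_C == Ti, ]
    d$absorbance[order(d$wavelength_nm)]
  }, numeric(length(wl))))
  structure(list(temperatures = temps, wavelength = wl, spectra = spectra,
                 T_JA_true = NA_real_, in_grid = NA),
            class = "absorbance_ramp")
}
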