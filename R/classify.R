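# Pixel and spectrum classification: J-aggregate vs monomer vs background,
# nucleolus masking, threshold calibration, area-fraction and
# stress-granule colocalization quantification.

#' Classifier parameters
#'
#' Intensity rules for pixel classification in the 565--585 nm aggregate
#' detection band of a 12-bit image. Pixels at or above
#' `aggregate_threshold` are J-aggregate; pixels between the background
#' floor and the threshold are monomer; the rest are background. Defaults:
#' threshold 400 counts (of 4095), monomer window 175--350 counts, and a
#' background floor of one third of the monomer window minimum.
#'
#' @param aggregate_threshold counts; inclusive (a pixel exactly at the
#'   threshold is aggregate).
#' @param monomer_window counts, c(min, max); must satisfy
#'   0 < max < aggregate_threshold <= full_scale.
#' @param full_scale counts full scale (4095 for 12-bit).
#' @param background_floor counts below which a pixel is background.
#' @return object of class `classifier_params`.
#' @export
classifier_params <- function(aggregate_threshold = 400,
                              monomer_window = c(175, 350),
                              full_scale = 4095,
                              background_floor = monomer_window[1] / 3) {
  if (!(monomer_window[2] > 0 && monomer_window[2] < aggregate_threshold &&
        aggregate_threshold <= full_scale))
    stopf("need 0 < monomer_window max < aggregate_threshold <= full_scale")
  structure(
    list(aggregate_threshold = aggregate_threshold,
         monomer_window = monomer_window,
         full_scale = full_scale,
         background_floor = background_floor),
    class = "classifier_params"
  )
}

#' Classify pixels into aggregate, monomer and background
#'
#' Applies the intensity rules of [classifier_params()] to the 565--585 nm
#' channel: a pixel is J-aggregate iff its aggregate-band intensity is at
#' or above the threshold and it is not excluded; monomer iff below the
#' threshold but at or above the background floor; background otherwise.
#' Excluded pixels (e.g. nucleoli from [mask_nucleoli()]) are always
#' background, preventing bright nucleolar monomer signal from being
#' counted as aggregate.
#'
#' @param image a [spectral_image()] with a channel covering 575 nm.
#' @param params a [classifier_params()].
#' @param exclude optional logical mask of excluded pixels.
#' @return integer class map matrix: 0 background, 1 monomer, 2 aggregate.
#' @export
classify_pixels <- function(image, params = classifier_params(),
                            exclude = NULL) {
  ch <- aggregate_channel(image)
  cm <- matrix(0L, nrow(ch), ncol(ch))
  cm[ch >= params$background_floor] <- 1L
  cm[ch >= params$aggregate_threshold] <- 2L
  if (!is.null(exclude)) {
    if (!identical(dim(exclude), dim(ch)))
      stopf("exclusion mask shape does not match the image")
    cm[exclude] <- 0L
  }
  cm
}

#' Detect nucleoli inside the nucleus for exclusion
#'
#' Bright sub-regions inside the nucleus would otherwise be misread as
#' aggregate signal; this finds them automatically with an Otsu threshold
#' computed over nucleus pixels of the aggregate-band channel, keeping
#' 8-connected bright components above a minimum size. A uniform nucleus
#' yields an empty mask.
#'
#' @param image a [spectral_image()].
#' @param nucleus_mask logical mask of the nucleus.
#' @param min_size minimum component size in pixels.
#' @param contrast_floor minimum ratio of bright-class mean to dim-class
#'   mean for the Otsu split to count as real structure (guards against
#'   splitting pure noise in a uniform nucleus).
#' @return logical mask of nucleolus pixels (empty if none detected or the
#'   nucleus mask is empty).
#' @export
mask_nucleoli <- function(image, nucleus_mask, min_size = 4L,
                          contrast_floor = 1.5) {
  ch <- aggregate_channel(image)
  out <- matrix(FALSE, nrow(ch), ncol(ch))
  if (is.null(nucleus_mask) || !any(nucleus_mask)) return(out)
  vals <- ch[nucleus_mask]
  thr <- otsu_threshold(vals)
  if (is.na(thr)) return(out)
  bright <- vals > thr
  if (!any(bright) || all(bright)) return(out)
  if (mean(vals[bright]) < contrast_floor * mean(vals[!bright])) return(out)
  cand <- nucleus_mask & ch > thr
  lab <- label_components(cand)
  if (max(lab) == 0L) return(out)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  out[lab %in% keep & lab > 0L] <- TRUE
  out
}

#' Classify an emission spectrum as aggregate or monomer
#'
#' Two-part criterion for the J-aggregate signature: the band-ratio score
#' (mean intensity in 565--585 nm over mean intensity in 600--620 nm) must
#' exceed `score_cutoff`, and the 575 nm peak must be locally sharp: the
#' mean over the 573--577 nm window must rise above the mean of its
#' +/- 5 nm shoulders (568--572 and 578--582 nm) by more than both
#' `prominence_factor` times the local noise SD (estimated
#' from first differences over 610--650 nm unless supplied) and
#' `rel_floor` times the peak height itself. The broad monomer band can
#' produce a band-ratio near 2 and, being concave, a small positive chord
#' prominence; the relative floor is what rejects it, since a band tens of
#' nanometres wide drops by far less than 5% over +/- 5 nm while the
#' narrow aggregate band loses most of its height.
#'
#' @param wavelength wavelengths in nm; must cover 540--650 nm at <= 5 nm
#'   spacing.
#' @param intensity intensities (same length).
#' @param score_cutoff band-ratio cutoff (default 1.5).
#' @param prominence_factor noise multiples the 575 nm prominence must
#'   exceed (default 3).
#' @param rel_floor minimum prominence as a fraction of the 575 nm peak
#'   height (default 0.05).
#' @param noise_sd known noise SD; if `NULL`, estimated from the data.
#' @return list with `class` ("aggregate" or "monomer"), `score`,
#'   `prominence`, `prominence_floor`.
#' @export
classify_spectrum <- function(wavelength, intensity, score_cutoff = 1.5,
                              prominence_factor = 3, rel_floor = 0.05,
                              noise_sd = NULL) {
  if (min(wavelength) > 540 || max(wavelength) < 650)
    stopf("spectrum must cover at least 540-650 nm")
  if (max(diff(sort(wavelength))) > 5)
    stopf("wavelength grid too sparse (> 5 nm spacing)")
  o <- order(wavelength)
  wl <- wavelength[o]; y <- intensity[o]
  band_mean <- function(lo, hi) mean(y[wl >= lo & wl <= hi])
  num <- band_mean(565, 585)
  # the 600-620 band of a pure aggregate is noise-dominated and its mean
  # can be ~0 or negative; floor it so the score stays finite and positive
  den <- max(band_mean(600, 620), 1e-3 * abs(num), .Machine$double.xmin)
  score <- num / den
  # local sharpness: mean height of the 575 nm peak window above its
  # +/- 5 nm shoulders (window means suppress single-point noise)
  y_peak <- band_mean(573, 577)
  prominence <- y_peak - (band_mean(568, 572) + band_mean(578, 582)) / 2
  if (is.null(noise_sd)) {
    tail_reg <- wl >= 610 & wl <= 650
    noise_sd <- stats::sd(diff(y[tail_reg])) / sqrt(2)
    if (!is.finite(noise_sd)) noise_sd <- 0
  }
  floor <- max(prominence_factor * noise_sd, rel_floor * abs(y_peak))
  cls <- if (score > score_cutoff && prominence > floor) "aggregate" else "monomer"
  list(class = cls, score = score, prominence = prominence,
       prominence_floor = floor)
}

#' Calibrate the aggregate intensity threshold from labelled spectra
#'
#' Scans candidate intensity levels and returns the lowest level L, above
#' the monomer window, such that every pixel whose aggregate-band intensity
#' is at or above L carries the sharp-peak J-aggregate signature (per
#' [classify_spectrum()]). This reproduces the iterative search for the
#' lowest level that reliably captures the narrow 575 nm peak.
#'
#' @param intensity per-pixel aggregate-band intensities (counts).
#' @param spectra list of data.frames (`wavelength_nm`, `intensity`), one
#'   per pixel.
#' @param params a [classifier_params()] supplying the monomer window.
#' @param levels candidate levels; defaults to the sorted unique
#'   intensities above the monomer window maximum.
#' @param ... passed to [classify_spectrum()].
#' @return the calibrated threshold in counts.
#' @export
calibrate_threshold <- function(intensity, spectra, params = classifier_params(),
                                levels = NULL, ...) {
  stopifnot(length(intensity) == length(spectra))
  is_agg <- vapply(spectra, function(s) {
    classify_spectrum(s$wavelength_nm, s$intensity, ...)$class == "aggregate"
  }, logical(1))
  if (!any(is_agg)) stopf("calibration failure: no aggregate signature in any spectrum")
  if (is.null(levels)) {
    levels <- sort(unique(intensity[intensity > params$monomer_window[2]]))
  } else {
    levels <- sort(levels[levels > params$monomer_window[2]])
  }
  if (length(levels) == 0L)
    stopf("calibration failure: no candidate level above the monomer window")
  for (L in levels) {
    sel <- intensity >= L
    if (any(sel) && all(is_agg[sel])) return(L)
  }
  stopf("calibration failure: no intensity level separates the classes")
}

#' Aggregate area fraction of the cytoplasm
#'
#' Percentage of cytoplasm pixels classified as J-aggregate:
#' `100 * |aggregate AND cytoplasm| / |cytoplasm|`.
#'
#' @param classmap class map from [classify_pixels()].
#' @param cytoplasm_mask logical mask; must be non-empty.
#' @return percentage in [0, 100].
#' @export
aggregate_area_fraction <- function(classmap, cytoplasm_mask) {
  if (!any(cytoplasm_mask)) stopf("empty cytoplasm mask: area fraction undefined")
  100 * sum(classmap == 2L & cytoplasm_mask) / sum(cytoplasm_mask)
}

#' Stress-granule colocalization
#'
#' Per-granule class content and monomer enrichment. For each granule the
#' fraction of its pixels in each class is reported together with the
#' ratio of its mean monomer-channel (600--620 nm) intensity to the mean
#' over cytoplasm pixels outside granules.
#'
#' @param classmap class map from [classify_pixels()].
#' @param image the [spectral_image()] (for the monomer channel).
#' @param granule_mask integer label matrix of granules (0 = none) or a
#'   logical mask (treated as one labelled set of connected granules).
#' @param cytoplasm_mask logical cytoplasm mask.
#' @return data.frame with one row per granule: `granule_id`, `n_px`,
#'   `frac_aggregate`, `frac_monomer`, `frac_background`,
#'   `monomer_enrichment`. Zero rows when there are no granules.
#' @export
colocalize_with_granules <- function(classmap, image, granule_mask,
                                     cytoplasm_mask) {
  if (is.logical(granule_mask)) granule_mask <- label_components(granule_mask)
  ids <- setdiff(sort(unique(as.vector(granule_mask))), 0L)
  mono <- monomer_channel(image)
  cyto_out <- cytoplasm_mask & granule_mask == 0L
  cyto_mean <- mean(mono[cyto_out])
  out <- data.frame(granule_id = integer(0), n_px = integer(0),
                    frac_aggregate = numeric(0), frac_monomer = numeric(0),
                    frac_background = numeric(0),
                    monomer_enrichment = numeric(0))
  for (g in ids) {
    sel <- granule_mask == g
    n <- sum(sel)
    out <- rbind(out, data.frame(
      granule_id = g, n_px = n,
      frac_aggregate = sum(classmap[sel] == 2L) / n,
      frac_monomer = sum(classmap[sel] == 1L) / n,
      frac_background = sum(classmap[sel] == 0L) / n,
      monomer_enrichment = mean(mono[sel]) / cyto_mean))
  }
  out
}
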