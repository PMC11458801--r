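#' Multichannel spectral image
#'
#' Container for a multichannel 2-D fluorescence raster with per-channel
#' emission-band metadata, as produced by spectral confocal imaging. The
#' three standard detection bands are 500--520 nm (FUS-GFP), 565--585 nm
#' (J-aggregate) and 600--620 nm (monomer).
#'
#' @param channels named list of integer matrices, all of the same shape.
#'   Names are free; bands carry the semantics.
#' @param bands numeric matrix with one row per channel and columns
#'   `lo`, `hi` (emission window in nm).
#' @param bit_depth full-scale intensity in counts (default 4095, 12-bit).
#' @param pixel_size pixel edge length in micrometres per pixel, or `NA`.
#'
#' @return An object of class `spectral_image`.
#' @export
spectral_image <- function(channels, bands, bit_depth = 4095, pixel_size = NA_real_) {
  if (!is.list(channels) || length(channels) == 0L)
    stopf("`channels` must be a non-empty list of matrices")
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1L) stopf("all channels must share the same shape")
  bands <- as.matrix(bands)
  if (nrow(bands) != length(channels) || ncol(bands) != 2L)
    stopf("`bands` must have one (lo, hi) row per channel")
  colnames(bands) <- c("lo", "hi")
  for (ch in channels) {
    if (any(ch < 0 | ch > bit_depth, na.rm = TRUE))
      stopf("channel intensities must lie in [0, %d]", bit_depth)
  }
  structure(
    list(channels = channels, bands = bands, bit_depth = bit_depth,
         pixel_size = pixel_size),
    class = "spectral_image"
  )
}

#' @export
print.spectral_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<spectral_image> %d x %d px, %d channels, full scale %d\n",
              d[1], d[2], length(x$channels), x$bit_depth))
  for (i in seq_along(x$channels)) {
    cat(sprintf("  channel %d: %g-%g nm\n", i, x$bands[i, 1], x$bands[i, 2]))
  }
  invisible(x)
}

# Index of the channel whose emission band contains `wavelength` nm.
channel_for_band <- function(image, wavelength) {
  hit <- which(image$bands[, "lo"] <= wavelength & image$bands[, "hi"] >= wavelength)
  if (length(hit) == 0L) return(NA_integer_)
  hit[1L]
}

# The 565-585 nm aggregate-band channel; errors if absent.
aggregate_channel <- function(image) {
  i <- channel_for_band(image, 575)
  if (is.na(i)) stopf("image has no channel covering the 575 nm aggregate band")
  image$channels[[i]]
}

# The 600-620 nm monomer-band channel; errors if absent.
monomer_channel <- function(image) {
  i <- channel_for_band(image, 610)
  if (is.na(i)) stopf("image has no channel covering the 600-620 nm monomer band")
  image$channels[[i]]
}

# The 500-520 nm FUS-GFP channel; errors if absent.
gfp_channel <- function(image) {
  i <- channel_for_band(image, 510)
  if (is.na(i)) stopf("image has no channel covering the 500-520 nm GFP band")
  image$channels[[i]]
}
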