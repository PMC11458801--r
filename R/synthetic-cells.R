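# Synthetic cell scenes with known ground truth.
#
# A scene is one cell: an elliptical cytoplasm containing an elliptical
# nucleus with bright nucleoli, optional stress granules in the cytoplasm,
# diffuse monomeric dye signal, and planted rod-shaped J-aggregate objects.
# The generator emits the three standard detection channels together with
# the compartment masks and a per-pixel ground-truth class map, so that
# downstream recovery tests never have to re-derive truth from the signal.

#' Describe a synthetic cell scene
#'
#' Parameters of a single-cell scene for [generate_cell_image()]. Defaults
#' reproduce the statistical structure the classifier assumes: diffuse
#' monomer signal averaging 250 counts (12-bit scale) in the aggregate
#' detection band, and bright fibrillar J-aggregate rods well above the
#' 400-count detection threshold.
#'
#' @param image_shape integer c(rows, cols) in pixels.
#' @param monomer_level mean diffuse monomer intensity in counts.
#' @param monomer_spread standard deviation of the diffuse signal (counts);
#'   0 gives a noiseless scene.
#' @param aggregate_peak peak intensity of planted rods in the 565--585 nm
#'   channel (counts).
#' @param rod_length,rod_width rod dimensions in pixels (length >> width,
#'   matching the fibrillar geometry of J-aggregates).
#' @param planted_aggregate_fraction target fraction of cytoplasm area
#'   covered by aggregate objects, in [0, 1].
#' @param n_granules number of stress granules planted in the cytoplasm.
#' @param granule_radius granule radius in pixels.
#' @param granule_enrichment multiplicative enrichment of monomer signal
#'   inside granules relative to cytoplasm.
#' @param n_nucleoli number of bright nucleoli inside the nucleus.
#' @param nucleolus_level mean nucleolus intensity (counts); bright enough
#'   to masquerade as aggregate unless masked.
#' @param pixel_size micrometres per pixel.
#' @param seed RNG seed; fixing it makes the scene bit-reproducible.
#'
#' @return An object of class `cell_scene`.
#' @export
cell_scene <- function(image_shape = c(192L, 192L),
                       monomer_level = 250,
                       monomer_spread = 15,
                       aggregate_peak = 1200,
                       rod_length = 18,
                       rod_width = 3,
                       planted_aggregate_fraction = 0,
                       n_granules = 0L,
                       granule_radius = 6,
                       granule_enrichment = 2,
                       n_nucleoli = 2L,
                       nucleolus_level = 900,
                       pixel_size = 0.2,
                       seed = NULL) {
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 48L))
    stopf("image too small to contain the requested compartments (min 48 x 48 px)")
  if (planted_aggregate_fraction < 0 || planted_aggregate_fraction > 1)
    stopf("planted_aggregate_fraction must lie in [0, 1]")
  if (monomer_level < 0 || monomer_level > 4095)
    stopf("monomer_level must lie in [0, 4095]")
  structure(
    list(image_shape = image_shape, monomer_level = monomer_level,
         monomer_spread = monomer_spread, aggregate_peak = aggregate_peak,
         rod_length = rod_length, rod_width = rod_width,
         planted_aggregate_fraction = planted_aggregate_fraction,
         n_granules = as.integer(n_granules), granule_radius = granule_radius,
         granule_enrichment = granule_enrichment,
         n_nucleoli = as.integer(n_nucleoli), nucleolus_level = nucleolus_level,
         pixel_size = pixel_size, seed = seed),
    class = "cell_scene"
  )
}

#' Generate a synthetic multichannel cell image with ground truth
#'
#' Renders a [cell_scene()] into a three-channel [spectral_image()]
#' (500--520, 565--585, 600--620 nm), compartment masks, and a ground-truth
#' class map marking the planted aggregate pixels. Rods are planted one by
#' one until the requested cytoplasm coverage is reached; pixels of the last
#' rod are trimmed so the planted fraction matches the target to within a
#' fraction of a percent. All intensities are integer counts clipped to
#' [0, 4095]; noise is Poisson-Gaussian (shot noise plus additive read
#' noise of `monomer_spread` counts) and is switched off entirely when
#' `monomer_spread = 0`.
#'
#' @param scene a [cell_scene()].
#' @return A list with elements:
#'   \describe{
#'     \item{image}{a [spectral_image()] with 3 channels}
#'     \item{rois}{list of logical masks: `cell`, `cytoplasm`, `nucleus`,
#'       `nucleoli`, `granules` (label matrix), `background_spots`}
#'     \item{truth}{integer class map: 0 background, 1 monomer, 2 aggregate}
#'     \item{planted_fraction}{achieved aggregate coverage of the cytoplasm}
#'   }
#' @export
generate_cell_image <- function(scene) {
  stopifnot(inherits(scene, "cell_scene"))
  shp <- scene$image_shape
  with_seed(scene$seed, {
    r0 <- (shp[1] - 1) / 2; c0 <- (shp[2] - 1) / 2
    cell <- ellipse_mask(shp, r0, c0, 0.42 * shp[1], 0.45 * shp[2])
    nucleus <- ellipse_mask(shp, r0 - 0.08 * shp[1], c0 - 0.05 * shp[2],
                            0.16 * shp[1], 0.18 * shp[2])
    nucleus <- nucleus & cell
    cytoplasm <- cell & !nucleus

    # nucleoli: bright discs strictly inside the nucleus
    nucleoli <- matrix(FALSE, shp[1], shp[2])
    if (scene$n_nucleoli > 0L) {
      nidx <- which(nucleus)
      nrows <- ((nidx - 1L) %% shp[1])
      ncols <- ((nidx - 1L) %/% shp[1])
      rad <- max(2, 0.03 * shp[1])
      for (i in seq_len(scene$n_nucleoli)) {
        repeat {
          j <- sample(length(nidx), 1L)
          d <- disc_mask(shp, nrows[j], ncols[j], rad)
          if (all(nucleus[d])) { nucleoli <- nucleoli | d; break }
        }
      }
    }

    # stress granules: discs in the cytoplasm, labelled 1..n
    granules <- matrix(0L, shp[1], shp[2])
    if (scene$n_granules > 0L) {
      cidx <- which(cytoplasm)
      crows <- ((cidx - 1L) %% shp[1])
      ccols <- ((cidx - 1L) %/% shp[1])
      g <- 0L
      tries <- 0L
      while (g < scene$n_granules && tries < 2000L) {
        tries <- tries + 1L
        j <- sample(length(cidx), 1L)
        d <- disc_mask(shp, crows[j], ccols[j], scene$granule_radius)
        if (all(cytoplasm[d]) && all(granules[d] == 0L)) {
          g <- g + 1L
          granules[d] <- g
        }
      }
      if (g < scene$n_granules)
        stopf("image too small to place %d granules", scene$n_granules)
    }

    # plant aggregate rods in the cytoplasm (outside granules) up to the
    # target coverage; trim the last rod to hit the pixel budget
    n_cyt <- sum(cytoplasm)
    target_px <- round(scene$planted_aggregate_fraction * n_cyt)
    agg <- matrix(FALSE, shp[1], shp[2])
    if (target_px > 0L) {
      cidx <- which(cytoplasm & granules == 0L)
      crows <- ((cidx - 1L) %% shp[1])
      ccols <- ((cidx - 1L) %/% shp[1])
      planted <- 0L
      tries <- 0L
      while (planted < target_px && tries < 50000L) {
        tries <- tries + 1L
        j <- sample(length(cidx), 1L)
        ang <- stats::runif(1, 0, pi)
        dr <- sin(ang) * scene$rod_length / 2
        dc <- cos(ang) * scene$rod_length / 2
        rod <- rod_mask(shp, crows[j] - dr, ccols[j] - dc,
                        crows[j] + dr, ccols[j] + dc, scene$rod_width)
        new_px <- which(rod & cytoplasm & !agg & granules == 0L)
        if (length(new_px) == 0L) next
        excess <- planted + length(new_px) - target_px
        if (excess > 0L) new_px <- new_px[seq_len(length(new_px) - excess)]
        agg[new_px] <- TRUE
        planted <- planted + length(new_px)
      }
    }

    noisy <- function(mean_map) {
      if (scene$monomer_spread == 0) return(clip12(mean_map))
      shot <- stats::rpois(length(mean_map), lambda = pmax(mean_map, 0))
      read <- stats::rnorm(length(mean_map), 0, scene$monomer_spread)
      clip12(matrix(shot + read, nrow(mean_map), ncol(mean_map)))
    }

    # 565-585 nm aggregate band: diffuse monomer everywhere in the cell,
    # nucleoli bright, rods at aggregate_peak
    ch_agg <- matrix(0, shp[1], shp[2])
    ch_agg[cell] <- scene$monomer_level
    ch_agg[nucleoli] <- scene$nucleolus_level
    ch_agg[agg] <- scene$aggregate_peak

    # 600-620 nm monomer band: diffuse signal, enriched in granules,
    # weak response to aggregates (narrow emission does not reach 600 nm)
    ch_mon <- matrix(0, shp[1], shp[2])
    ch_mon[cell] <- 0.5 * scene$monomer_level
    ch_mon[granules > 0L] <- 0.5 * scene$monomer_level * scene$granule_enrichment
    ch_mon[nucleoli] <- 0.5 * scene$nucleolus_level

    # 500-520 nm GFP band: granules bright (FUS-GFP), faint cytoplasm
    ch_gfp <- matrix(0, shp[1], shp[2])
    ch_gfp[cell] <- 120
    ch_gfp[nucleus] <- 200
    ch_gfp[granules > 0L] <- 1500

    image <- spectral_image(
      channels = list(gfp = noisy(ch_gfp), aggregate = noisy(ch_agg),
                      monomer = noisy(ch_mon)),
      bands = rbind(c(500, 520), c(565, 585), c(600, 620)),
      bit_depth = 4095, pixel_size = scene$pixel_size
    )

    truth <- matrix(0L, shp[1], shp[2])
    truth[cell] <- 1L
    truth[agg] <- 2L

    # 10 background spots outside the cell, for background correction
    bg_spots <- matrix(0L, shp[1], shp[2])
    out <- which(!cell)
    orows <- ((out - 1L) %% shp[1])
    ocols <- ((out - 1L) %/% shp[1])
    s <- 0L; tries <- 0L
    while (s < 10L && tries < 5000L) {
      tries <- tries + 1L
      j <- sample(length(out), 1L)
      d <- disc_mask(shp, orows[j], ocols[j], 3)
      if (all(!cell[d]) && all(bg_spots[d] == 0L)) { s <- s + 1L; bg_spots[d] <- s }
    }

    list(
      image = image,
      rois = list(cell = cell, cytoplasm = cytoplasm, nucleus = nucleus,
                  nucleoli = nucleoli, granules = granules,
                  background_spots = bg_spots),
      truth = truth,
      planted_fraction = sum(agg) / n_cyt
    )
  })
}
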