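# Droplet / stress-granule morphometrics: threshold segmentation, area,
# circularity, background-corrected mean intensity, and group summaries
# with significance tests.

#' Segment objects at an intensity threshold
#'
#' Without seeds: all 8-connected components of pixels at or above
#' `threshold`, discarding components smaller than `min_size` (default 4 px,
#' suppressing shot-noise specks). With seeds: a flood fill of connected
#' above-threshold pixels from each seed point, emulating wand-tool
#' selection; a seed on a below-threshold pixel yields no region.
#'
#' @param raster numeric intensity matrix.
#' @param threshold counts; inclusive.
#' @param seeds optional integer matrix/data.frame of seed pixels with
#'   columns `row`, `col` (1-based).
#' @param min_size minimum object size in pixels (ignored for seeded
#'   selection).
#' @return integer label matrix (0 = background). For seeded selection,
#'   labels follow seed order; seeds falling in the same component share
#'   the first seed's label.
#' @export
segment_objects <- function(raster, threshold, seeds = NULL, min_size = 4L) {
  mask <- raster >= threshold
  lab_all <- label_components(mask)
  if (is.null(seeds)) {
    if (max(lab_all) == 0L) return(lab_all)
    sizes <- tabulate(lab_all[lab_all > 0L])
    keep <- which(sizes >= min_size)
    out <- matrix(0L, nrow(raster), ncol(raster))
    new_id <- 0L
    for (k in keep) {
      new_id <- new_id + 1L
      out[lab_all == k] <- new_id
    }
    return(out)
  }
  seeds <- as.matrix(seeds)
  out <- matrix(0L, nrow(raster), ncol(raster))
  next_id <- 0L
  assigned <- integer(0)  # component id -> output label
  for (i in seq_len(nrow(seeds))) {
    r <- seeds[i, 1]; cl <- seeds[i, 2]
    comp <- lab_all[r, cl]
    if (comp == 0L) next  # seed below threshold: empty region
    if (comp %in% names(assigned)) next
    next_id <- next_id + 1L
    assigned[as.character(comp)] <- next_id
    out[lab_all == comp] <- next_id
  }
  out
}

#' Circularity shape descriptor
#'
#' `4 pi A / P^2`, capped at 1. Equals 1 for a circle, pi/4 for a square
#' (with analytic perimeter), and decreases for elongated or irregular
#' shapes.
#'
#' @param area area (any consistent unit).
#' @param perimeter perimeter (same length unit).
#' @return circularity in (0, 1].
#' @export
circularity <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0)) stopf("area and perimeter must be positive")
  pmin(4 * pi * area / perimeter^2, 1)
}

#' Measure labelled objects
#'
#' Per-object area, perimeter (Kulpa-corrected chain-code estimate from
#' Moore boundary tracing), circularity and mean intensity. When the pixel
#' size is known, areas and perimeters are additionally reported in
#' micrometre units.
#'
#' @param labels integer label matrix from [segment_objects()].
#' @param raster intensity matrix for mean intensities.
#' @param pixel_size micrometres per pixel, or `NA` for pixel units only.
#' @return data.frame with columns `object_id`, `area_px`, `perimeter_px`,
#'   `circularity`, `mean_intensity`, and (if pixel_size given) `area_um2`,
#'   `perimeter_um`.
#' @export
measure_objects <- function(labels, raster, pixel_size = NA_real_) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  rows <- lapply(ids, function(k) {
    m <- labels == k
    a <- sum(m)
    p <- perimeter_estimate(m)
    data.frame(object_id = k, area_px = a, perimeter_px = p,
               circularity = circularity(a, p),
               mean_intensity = mean(raster[m]))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(object_id = integer(0), area_px = numeric(0),
               perimeter_px = numeric(0), circularity = numeric(0),
               mean_intensity = numeric(0))
  if (!is.na(pixel_size)) {
    out$area_um2 <- out$area_px * pixel_size^2
    out$perimeter_um <- out$perimeter_px * pixel_size
  }
  out
}

#' Background-correct object intensities
#'
#' Subtracts the arithmetic mean of the background-spot means from each
#' object's mean intensity. Spots overlapping a segmented object are
#' excluded with a warning.
#'
#' @param records data.frame from [measure_objects()].
#' @param raster intensity matrix.
#' @param background_spots integer label matrix of background spots
#'   (conventionally 10), or logical mask (labelled by connectivity).
#' @param labels object label matrix used to detect spot/object overlap
#'   (optional).
#' @return `records` with an added `corrected_intensity` column and an
#'   attribute `background_mean`.
#' @export
background_correct <- function(records, raster, background_spots,
                               labels = NULL) {
  if (is.logical(background_spots))
    background_spots <- label_components(background_spots)
  ids <- setdiff(sort(unique(as.vector(background_spots))), 0L)
  if (length(ids) == 0L) stopf("need at least one background spot")
  spot_means <- numeric(0)
  for (s in ids) {
    sel <- background_spots == s
    if (!is.null(labels) && any(labels[sel] > 0L)) {
      warnf("background spot %d overlaps a segmented object: excluded", s)
      next
    }
    spot_means <- c(spot_means, mean(raster[sel]))
  }
  if (length(spot_means) == 0L)
    stopf("all background spots overlap objects")
  bg <- mean(spot_means)
  records$corrected_intensity <- records$mean_intensity - bg
  attr(records, "background_mean") <- bg
  records
}

#' Summarize grouped measurements with boxplot statistics and tests
#'
#' Per group: n, 5th percentile, first quartile, median, third quartile and
#' 95th percentile (type-7 linear-interpolation quantiles). Between groups:
#' a two-tailed Welch t-test for exactly two groups and a one-way ANOVA for
#' two or more.
#'
#' @param values numeric measurements.
#' @param groups group labels (same length).
#' @param tests if `TRUE` (default), between-group tests are required and a
#'   single group is an error; with `FALSE` a single group yields summary
#'   statistics only.
#' @return list with `stats` (data.frame, one row per group), `t_test`
#'   (htest or NULL), `anova` (list with `F`, `p`, df or NULL).
#' @export
summarize_groups <- function(values, groups, tests = TRUE) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 1L) stopf("no groups")
  split_vals <- split(values, groups)
  if (any(vapply(split_vals, length, integer(1)) < 3L))
    stopf("need at least 3 records per group for quartiles")
  qs <- t(vapply(split_vals, stats::quantile,
                 probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
                 type = 7, numeric(5)))
  stats_df <- data.frame(
    group = names(split_vals),
    n = vapply(split_vals, length, integer(1)),
    p05 = qs[, 1], q1 = qs[, 2], median = qs[, 3], q3 = qs[, 4], p95 = qs[, 5],
    mean = vapply(split_vals, mean, numeric(1)),
    sd = vapply(split_vals, stats::sd, numeric(1)),
    row.names = NULL
  )
  t_res <- NULL
  if (nlevels(groups) == 2L) {
    t_res <- stats::t.test(split_vals[[1]], split_vals[[2]],
                           alternative = "two.sided")
  }
  a_res <- NULL
  if (nlevels(groups) >= 2L) {
    fit <- stats::aov(values ~ groups)
    s <- summary(fit)[[1]]
    a_res <- list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
                  df_between = s[["Df"]][1], df_within = s[["Df"]][2])
  } else if (tests) {
    stopf("between-group tests require at least 2 groups")
  }
  list(stats = stats_df, t_test = t_res, anova = a_res)
}
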