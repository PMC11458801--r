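# Segmentation, circularity, background correction and group summaries.

test_that("threshold segmentation respects connectivity and minimum size", {
  img <- matrix(10, 50, 50)
  expect_equal(max(segment_objects(img, 100)), 0L)  # nothing above threshold

  shape <- c(50, 50)
  img[picquant:::disc_mask(shape, 12, 12, 6)] <- 500
  img[picquant:::disc_mask(shape, 35, 35, 4)] <- 500
  lab <- segment_objects(img, 400)
  expect_equal(max(lab), 2L)
  expect_equal(sum(lab == 1L), sum(picquant:::disc_mask(shape, 12, 12, 6)))

  # a bridge above threshold merges the discs into one object
  img[12, 12:35] <- 500; img[12:35, 35] <- 500
  expect_equal(max(segment_objects(img, 400)), 1L)
})

test_that("seeded segmentation emulates wand-tool selection", {
  img <- matrix(0, 40, 40)
  img[picquant:::disc_mask(c(40, 40), 10, 10, 5)] <- 800
  img[picquant:::disc_mask(c(40, 40), 30, 30, 5)] <- 800
  lab <- segment_objects(img, 400, seeds = rbind(c(11, 11), c(5, 38)))
  expect_equal(sum(lab == 1L), sum(picquant:::disc_mask(c(40, 40), 10, 10, 5)))
  # second seed lies below threshold: contributes no region
  expect_equal(max(lab), 1L)
})

test_that("circularity matches closed forms and raster estimates", {
  # analytic square: 4 pi s^2 / (4s)^2 = pi/4
  s <- 7.3
  expect_equal(circularity(s^2, 4 * s), pi / 4)
  # 2:1 ellipse with Ramanujan perimeter: ~0.84
  a <- 2; b <- 1
  h <- ((a - b) / (a + b))^2
  per <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  expect_equal(round(circularity(pi * a * b, per), 2), 0.84)
  # large rasterized disc: 1.00 +/- 0.05 through the raster pipeline
  m <- picquant:::disc_mask(c(121, 121), 60, 60, 50)
  rec <- measure_objects(matrix(as.integer(m), 121, 121), m * 100)
  expect_lt(abs(rec$circularity - 1), 0.05)
  # degenerate single pixel: 1 by convention
  one <- matrix(0L, 5, 5); one[3, 3] <- 1L
  expect_equal(measure_objects(one, one * 100)$circularity, 1)
})

test_that("circularity is scale invariant and areas scale with pixel size", {
  circ_of_ellipse <- function(scale) {
    shape <- c(8 * scale + 1, 8 * scale + 1) * 2
    m <- picquant:::ellipse_mask(shape, shape[1] / 2, shape[2] / 2,
                                 2 * scale, 4 * scale)
    measure_objects(matrix(as.integer(m), shape[1], shape[2]), m * 1)$circularity
  }
  c1 <- circ_of_ellipse(20)
  c2 <- circ_of_ellipse(40)
  expect_lt(abs(c1 - c2), 0.02)

  m <- picquant:::disc_mask(c(30, 30), 15, 15, 8)
  rec <- measure_objects(matrix(as.integer(m), 30, 30), m * 1, pixel_size = 0.25)
  expect_equal(rec$area_um2, rec$area_px * 0.25^2)
  expect_equal(rec$area_px, sum(m))  # exact integer pixel count preserved
})

test_that("background correction subtracts the mean of spot means", {
  img <- matrix(40, 60, 60)
  obj <- picquant:::disc_mask(c(60, 60), 30, 30, 8)
  img[obj] <- 500
  labels <- matrix(as.integer(obj), 60, 60)
  spots <- matrix(0L, 60, 60)
  means <- numeric(0)
  for (s in 1:10) {
    r0 <- 5 + ((s - 1) %% 5) * 11; c0 <- 5 + ((s - 1) %/% 5) * 40
    sel <- picquant:::disc_mask(c(60, 60), r0, c0, 2)
    img[sel] <- 40 + s          # known spot levels
    spots[sel & spots == 0L & !obj] <- s
  }
  rec <- measure_objects(labels, img)
  cor <- background_correct(rec, img, spots, labels)
  spot_means <- vapply(1:10, function(s) mean(img[spots == s]), numeric(1))
  expect_equal(attr(cor, "background_mean"), mean(spot_means))
  expect_equal(cor$corrected_intensity, cor$mean_intensity - mean(spot_means))

  # zero background leaves intensities untouched
  img0 <- img; img0[spots > 0L] <- 0
  cor0 <- background_correct(rec, img0, spots, labels)
  expect_equal(cor0$corrected_intensity, cor0$mean_intensity)

  # spot overlapping the object is excluded with a warning
  spots_bad <- spots; spots_bad[obj][1:5] <- 11L
  expect_warning(background_correct(rec, img, spots_bad, labels), "overlaps")
})

test_that("group summaries match sort-based quantiles exactly", {
  set.seed(42)
  x <- rnorm(101)
  res <- summarize_groups(c(x, x + 1), rep(c("a", "b"), each = 101))
  for (p in c(0.05, 0.25, 0.5, 0.75, 0.95)) {
    col <- c("0.05" = "p05", "0.25" = "q1", "0.5" = "median",
             "0.75" = "q3", "0.95" = "p95")[[as.character(p)]]
    expect_equal(res$stats[res$stats$group == "a", col],
                 oracle_quantile7(x, p), tolerance = 1e-14)
  }
})

test_that("degenerate and identical groups behave as expected", {
  # identical groups: t = 0, p = 1
  x <- c(1.2, 3.4, 2.2, 5.0, 0.7)
  res <- summarize_groups(c(x, x), rep(c("a", "b"), each = 5))
  expect_equal(unname(res$t_test$statistic), 0)
  expect_equal(res$t_test$p.value, 1)
  # constant group: all quantiles equal the constant
  resc <- summarize_groups(c(rep(7, 5), x), rep(c("c", "x"), each = 5))
  row <- resc$stats[resc$stats$group == "c", ]
  expect_true(all(row[c("p05", "q1", "median", "q3", "p95")] == 7))
  # single group with tests requested is an error
  expect_error(summarize_groups(x, rep("only", 5)), "2 groups")
  # but summary-only mode works
  expect_silent(summarize_groups(x, rep("only", 5), tests = FALSE))
})

test_that("a 3-sigma mean shift at n = 50 is detected nearly always", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    a <- rnorm(50, 0, 1); b <- rnorm(50, 3, 1)
    res <- summarize_groups(c(a, b), rep(c("a", "b"), each = 50))
    res$t_test$p.value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
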