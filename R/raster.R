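# Low-level raster utilities: mask rasterization, connected-component
# labelling, Otsu thresholding and boundary-length estimation.
#
# No image-analysis package ships with the target R stack, so the small set
# of primitives the pipeline needs is implemented here. Masks are logical
# matrices, label images are integer matrices (0 = background), indexed
# [row, col] with 0-based pixel centres at (row - 1, col - 1).

# Logical disc mask: centre (r0, c0), radius in pixels.
disc_mask <- function(shape, r0, c0, radius) {
  rr <- matrix(seq_len(shape[1]) - 1, shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]) - 1, shape[1], shape[2], byrow = TRUE)
  (rr - r0)^2 + (cc - c0)^2 <= radius^2
}

# Axis-aligned ellipse mask with semi-axes (a_row, a_col).
ellipse_mask <- function(shape, r0, c0, a_row, a_col) {
  rr <- matrix(seq_len(shape[1]) - 1, shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]) - 1, shape[1], shape[2], byrow = TRUE)
  ((rr - r0) / a_row)^2 + ((cc - c0) / a_col)^2 <= 1
}

# Pixels within `width/2` of the segment (r1,c1)-(r2,c2): a rasterized rod.
rod_mask <- function(shape, r1, c1, r2, c2, width) {
  rr <- matrix(seq_len(shape[1]) - 1, shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]) - 1, shape[1], shape[2], byrow = TRUE)
  dr <- r2 - r1; dc <- c2 - c1
  len2 <- dr * dr + dc * dc
  if (len2 == 0) return(disc_mask(shape, r1, c1, width / 2))
  t <- ((rr - r1) * dr + (cc - c1) * dc) / len2
  t[t < 0] <- 0; t[t > 1] <- 1
  d2 <- (rr - (r1 + t * dr))^2 + (cc - (c1 + t * dc))^2
  d2 <= (width / 2)^2
}

# 8-connected component labelling by breadth-first flood fill.
# Returns an integer matrix; components numbered in raster-scan order of
# their first pixel, so labelling is deterministic.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  # neighbour offsets in linear (column-major) index space, guarded per-pixel
  current <- 0L
  queue <- integer(length(idx))
  for (start in idx) {
    if (lab[start] != 0L) next
    current <- current + 1L
    lab[start] <- current
    queue[1L] <- start
    head <- 1L; tail <- 1L
    while (head <= tail) {
      p <- queue[head]; head <- head + 1L
      r <- ((p - 1L) %% nr) + 1L
      cl <- ((p - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        r2 <- r + dr; c2 <- cl + dc
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        p2 <- (c2 - 1L) * nr + r2
        if (mask[p2] && lab[p2] == 0L) {
          lab[p2] <- current
          tail <- tail + 1L
          queue[tail] <- p2
        }
      }
    }
  }
  lab
}

# Otsu's between-class-variance threshold on integer counts.
# Returns the threshold t such that x > t is "bright".
otsu_threshold <- function(x) {
  x <- as.integer(round(x))
  lo <- min(x); hi <- max(x)
  if (lo == hi) return(NA_real_)
  h <- tabulate(x - lo + 1L, nbins = hi - lo + 1L)
  p <- h / sum(h)
  levels <- seq.int(lo, hi)
  w1 <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  levels[which.max(sigma_b)]
}

# Moore-neighbour boundary tracing of a single 8-connected region.
# Returns counts of straight and diagonal chain-code steps along the
# closed outer boundary.
trace_boundary <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L) stopf("empty region")
  if (length(idx) == 1L) return(list(n_straight = 0L, n_diag = 0L))
  nr <- nrow(mask); nc <- ncol(mask)
  # clockwise neighbourhood starting at W: (dr, dc)
  drs <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dcs <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dir_of <- function(dr, dc) which(drs == dr & dcs == dc)
  inside <- function(r, cl) r >= 1L && r <= nr && cl >= 1L && cl <= nc && mask[r, cl]
  # start: topmost, then leftmost foreground pixel; its W neighbour is bg
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  o <- order(rows, cols)
  sr <- rows[o[1L]]; sc <- cols[o[1L]]
  r <- sr; cl <- sc
  dir_b <- 1L  # direction from current pixel to its backtrack (W initially)
  state0 <- c(sr, sc, dir_b)
  n_straight <- 0L; n_diag <- 0L
  max_steps <- 8L * length(idx) + 16L
  steps <- 0L
  repeat {
    found <- FALSE
    for (k in 1:8) {
      d <- ((dir_b - 1L + k) %% 8L) + 1L
      r2 <- r + drs[d]; c2 <- cl + dcs[d]
      if (inside(r2, c2)) {
        if (drs[d] != 0L && dcs[d] != 0L) n_diag <- n_diag + 1L
        else n_straight <- n_straight + 1L
        # backtrack of the new pixel = last background cell checked
        d_prev <- ((dir_b - 1L + k - 1L) %% 8L) + 1L
        dir_b <- dir_of(drs[d_prev] - drs[d], dcs[d_prev] - dcs[d])
        r <- r2; cl <- c2
        found <- TRUE
        break
      }
    }
    if (!found) break  # cannot happen for an 8-connected region of size > 1
    steps <- steps + 1L
    if (r == state0[1L] && cl == state0[2L] && dir_b == state0[3L]) break
    if (steps > max_steps) break
  }
  list(n_straight = n_straight, n_diag = n_diag)
}

# Kulpa's corrected chain-code perimeter estimator. Raw chain-code length
# (1 per straight step, sqrt(2) per diagonal) overestimates smooth contours
# by ~5.5%; the pi*(1+sqrt(2))/8 factor removes the bias for discs.
perimeter_estimate <- function(mask) {
  steps <- trace_boundary(mask)
  if (steps$n_straight + steps$n_diag == 0L) {
    # single-pixel region: perimeter chosen so circularity is exactly 1
    return(2 * sqrt(pi))
  }
  kulpa <- pi * (1 + sqrt(2)) / 8
  kulpa * (steps$n_straight + sqrt(2) * steps$n_diag)
}
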