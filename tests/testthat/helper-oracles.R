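# Independent brute-force oracles used to cross-check the indexed
# implementation. Deliberately written as plain double loops over all
# pairs, with their own mask-membership and direction-sampling code.

withr_tempdir <- function() {
  d <- tempfile("sodamap")
  dir.create(d, recursive = TRUE)
  d
}

oracle_inside <- function(mask, p) {
  ps <- mask$pixel_size
  dm <- dim(mask$grid)
  cx <- floor(p[1] / ps["x"])
  cy <- floor(p[2] / ps["y"])
  if (cx < 0 || cy < 0 || cx >= dm[2] || cy >= dm[1]) return(FALSE)
  if (mask$dim == 3) {
    cz <- floor(p[3] / ps["z"])
    if (cz < 0 || cz >= dm[3]) return(FALSE)
    return(mask$grid[cy + 1, cx + 1, cz + 1])
  }
  mask$grid[cy + 1, cx + 1]
}

oracle_weight <- function(mask, p, d) {
  M <- if (mask$dim == 2) 360L else 512L
  if (mask$dim == 2) {
    inside <- vapply(0:(M - 1), function(m) {
      th <- (2 * pi * m) / M
      oracle_inside(mask, p + d * c(cos(th), sin(th)))
    }, logical(1))
  } else {
    ga <- pi * (3 - sqrt(5))
    inside <- vapply(0:(M - 1), function(m) {
      z <- 1 - 2 * (m + 0.5) / M
      r <- sqrt(max(0, 1 - z^2))
      oracle_inside(mask, p + d * c(r * cos(ga * m), r * sin(ga * m), z))
    }, logical(1))
  }
  frac <- max(mean(inside), 0.05)
  1 / frac
}

# explicit O(N^2) ring-wise corrected Ripley statistic
oracle_khat <- function(spots1, spots2, rings, mask) {
  radii <- rings$radii
  K <- length(radii) - 1
  acc <- numeric(K)
  for (i in seq_len(spots1$n)) {
    for (j in seq_len(spots2$n)) {
      d <- sqrt(sum((spots1$positions[i, ] - spots2$positions[j, ])^2))
      if (d >= radii[K + 1]) next
      k <- findInterval(d, radii)
      acc[k] <- acc[k] + oracle_weight(mask, spots1$positions[i, ], d)
    }
  }
  acc * mask$measure / (spots1$n * spots2$n)
}

# all cross pairs below rmax by brute force, for the spatial-index check
oracle_pairs <- function(spots1, spots2, rmax) {
  out <- NULL
  for (i in seq_len(spots1$n)) {
    for (j in seq_len(spots2$n)) {
      d <- sqrt(sum((spots1$positions[i, ] - spots2$positions[j, ])^2))
      if (d < rmax) out <- rbind(out, c(i, j, d))
    }
  }
  if (is.null(out)) return(data.frame(i = integer(0), j = integer(0),
                                      d = numeric(0)))
  out <- data.frame(i = out[, 1], j = out[, 2], d = out[, 3])
  out[order(out$i, out$j), , drop = FALSE]
}

# exhaustive 1D two-class threshold minimizing within-class variance on
# the same 256-bin histogram (oracle for K = 2 K-means thresholds)
oracle_otsu_like <- function(channel) {
  v <- as.numeric(channel)
  br <- seq(min(v), max(v), length.out = 257)
  mid <- (br[-1] + br[-257]) / 2
  bin <- pmin(pmax(findInterval(v, br, rightmost.closed = TRUE), 1L), 256L)
  w <- tabulate(bin, 256)
  best <- c(NA, Inf)
  for (t in 1:255) {
    lo <- w[1:t]; hi <- w[(t + 1):256]
    if (sum(lo) == 0 || sum(hi) == 0) next
    mlo <- sum(lo * mid[1:t]) / sum(lo)
    mhi <- sum(hi * mid[(t + 1):256]) / sum(hi)
    wcv <- sum(lo * (mid[1:t] - mlo)^2) + sum(hi * (mid[(t + 1):256] - mhi)^2)
    # the objective is flat across empty-histogram gaps; report the
    # class-mean midpoint (the fixed point of the split) to break ties
    if (wcv < best[2] - 1e-9) best <- c((mlo + mhi) / 2, wcv)
  }
  best[1]
}

# greedy matching of detected spot positions to ground truth within a
# radius; returns recall and precision
match_detections <- function(truth_pos, det_pos, radius) {
  if (nrow(det_pos) == 0)
    return(c(recall = 0, precision = NA_real_))
  used <- rep(FALSE, nrow(det_pos))
  hits <- 0
  for (i in seq_len(nrow(truth_pos))) {
    dd <- sqrt(rowSums((det_pos - matrix(truth_pos[i, ], nrow(det_pos),
                                         ncol(truth_pos), byrow = TRUE))^2))
    dd[used] <- Inf
    j <- which.min(dd)
    if (dd[j] <= radius) {
      used[j] <- TRUE
      hits <- hits + 1
    }
  }
  c(recall = hits / nrow(truth_pos), precision = hits / nrow(det_pos))
}

# noiseless isotropic Gaussian spot image (amplitude at the peak)
gaussian_spot_image <- function(ny, nx, centers_px, sigma = 2,
                                amplitude = 100, offset = 0) {
  img <- matrix(offset, ny, nx)
  for (k in seq_len(nrow(centers_px))) {
    gx <- exp(-((seq_len(nx) - 0.5 - centers_px[k, 1])^2) / (2 * sigma^2))
    gy <- exp(-((seq_len(ny) - 0.5 - centers_px[k, 2])^2) / (2 * sigma^2))
    img <- img + amplitude * outer(gy, gx)
  }
  img
}
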