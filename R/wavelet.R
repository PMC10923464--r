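# Undecimated a-trous wavelet decomposition and spot detection.
#
# The decomposition convolves the image with the separable B3-spline kernel
# (1/16, 1/4, 3/8, 1/4, 1/16), inserting 2^(s-1)-1 zeros between taps at
# scale s (mirror boundary). Detail planes W_s = A_{s-1} - A_s telescope, so
# sum(W_s) + A_S reconstructs the input exactly; spot-sized structure
# concentrates in the low scales (W_2 for diameters of ~2-6 px).

B3_TAPS <- c(1, 4, 6, 4, 1) / 16

mirror_index <- function(i, n) {
  # reflect indices (1-based) into [1, n]: ... 3 2 | 1 2 ... n | n-1 n-2 ...
  if (n == 1) return(rep(1L, length(i)))
  p <- (i - 1) %% (2 * n - 2)
  ifelse(p < n, p + 1, 2 * n - p - 1)
}

# separable convolution with the zero-inserted B3 kernel along every axis
b3_smooth <- function(a, step) {
  d <- dim(a)
  for (axis in seq_along(d)) {
    n <- d[axis]
    acc <- array(0, d)
    for (t in seq_along(B3_TAPS)) {
      off <- (t - 3) * step
      src <- mirror_index(seq_len(n) + off, n)
      args <- rep(list(quote(expr = )), length(d))
      args[[axis]] <- src
      acc <- acc + B3_TAPS[t] * do.call(`[`, c(list(a), args, list(drop = FALSE)))
    }
    a <- acc
  }
  a
}

#' A-trous wavelet decomposition
#'
#' @param channel nonnegative numeric matrix or 3D array (one image
#'   channel).
#' @param S number of scales (>= 1).
#' @return list with `planes` (list of S detail arrays `W_1..W_S`) and
#'   `residual` (the smooth approximation `A_S`); `Reduce("+", planes) +
#'   residual` equals `channel` to float tolerance.
#' @export
atrous_wavelet <- function(channel, S = 2) {
  if (is.null(dim(channel))) stop("channel must be a matrix or array")
  stopifnot(S >= 1)
  support <- 1 + 4 * 2^(S - 1) # kernel extent at the coarsest scale
  if (any(dim(channel) < 1) || min(dim(channel)) < 2)
    stop("grid too small for the kernel support")
  if (support > 2 * max(dim(channel)))
    stop("S too large: kernel support exceeds grid extent")
  A <- channel
  planes <- vector("list", S)
  for (s in seq_len(S)) {
    A_next <- b3_smooth(A, step = 2^(s - 1))
    planes[[s]] <- A - A_next
    A <- A_next
  }
  list(planes = planes, residual = A)
}

#' Spot-detection parameters
#'
#' @param scales wavelet scales whose thresholded detail planes must all
#'   support a voxel (default 2, matching spot diameters of roughly 2-6
#'   px).
#' @param k_sigma threshold multiplier on the robust per-scale noise level
#'   (default 3).
#' @param min_size_px minimum connected-component size in voxels (default
#'   2).
#' @return A `detection_params` list.
#' @export
detection_params <- function(scales = 2, k_sigma = 3, min_size_px = 2) {
  scales <- sort(unique(as.integer(scales)))
  stopifnot(length(scales) >= 1, all(scales >= 1), k_sigma > 0,
            min_size_px >= 1)
  structure(list(scales = scales, k_sigma = k_sigma,
                 min_size_px = as.integer(min_size_px)),
            class = "detection_params")
}

#' Detect spots in one channel by wavelet thresholding
#'
#' The per-scale noise level is the median absolute detail coefficient
#' divided by 0.6745 (a robust sigma estimate), computed inside the mask
#' when one is given. Voxels whose detail coefficients exceed
#' `k_sigma * sigma_s` at every selected scale are kept; full-connectivity
#' components of at least `min_size_px` voxels become spots, positioned at
#' their intensity-weighted centroid (weights are the original channel
#' values) in nm. Centroids falling outside the mask are discarded.
#'
#' @param channel numeric matrix or 3D array.
#' @param params a [detection_params()] list.
#' @param pixel_size nm per pixel (scalar or named per axis).
#' @param mask optional [cell_mask()] restricting noise estimation and
#'   output spots.
#' @param channel_id label stored on the result.
#' @return A [spot_set()] (empty for an all-zero channel).
#' @export
detect_spots <- function(channel, params = detection_params(),
                         pixel_size = 100, mask = NULL,
                         channel_id = "ch") {
  if (is.null(dim(channel)) || length(channel) == 0) stop("empty grid")
  d <- length(dim(channel))
  ps <- check_pixel_size(pixel_size, d)
  if (all(channel == 0))
    return(spot_set(matrix(numeric(0), 0, d), channel_id = channel_id))
  S <- max(params$scales)
  wt <- atrous_wavelet(channel, S = S)
  keep <- array(TRUE, dim(channel))
  inside <- if (!is.null(mask)) mask$grid else NULL
  for (s in params$scales) {
    W <- wt$planes[[s]]
    coefs <- if (is.null(inside)) W else W[inside]
    sigma_s <- median(abs(coefs)) / 0.6745
    keep <- keep & (W > params$k_sigma * sigma_s)
  }
  lab <- label_components(keep)
  nlab <- max(lab)
  if (nlab == 0)
    return(spot_set(matrix(numeric(0), 0, d), channel_id = channel_id))
  vox <- which(lab > 0)
  labs <- lab[vox]
  sizes <- tabulate(labs, nlab)
  ok_lab <- which(sizes >= params$min_size_px)
  if (length(ok_lab) == 0)
    return(spot_set(matrix(numeric(0), 0, d), channel_id = channel_id))
  sel <- labs %in% ok_lab
  vox <- vox[sel]
  labs <- labs[sel]
  idx <- arrayInd(vox, dim(channel))
  wts <- pmax(channel[vox], 0) + 1e-12
  g <- match(labs, ok_lab)
  wsum <- tapply_sum(wts, g, length(ok_lab))
  centroid_px <- sapply(seq_len(d), function(a)
    tapply_sum(wts * (idx[, a] - 0.5), g, length(ok_lab)) / wsum)
  centroid_px <- matrix(centroid_px, ncol = d)
  # (row, col[, slice]) half-pixel coordinates -> nm (x from col, y from row)
  pos <- cbind(x = centroid_px[, 2] * ps["x"], y = centroid_px[, 1] * ps["y"])
  if (d == 3) pos <- cbind(pos, z = centroid_px[, 3] * ps["z"])
  intensity <- tapply_sum(channel[vox], g, length(ok_lab))
  spots <- spot_set(pos, intensity = intensity, size = sizes[ok_lab],
                    channel_id = channel_id)
  if (!is.null(mask)) {
    if (mask$dim != d) stop("dimension mismatch between mask and channel")
    keep_spot <- mask_contains(mask, spots$positions)
    spots <- subset_spots(spots, keep_spot)
  }
  spots
}

tapply_sum <- function(x, g, nlev) {
  out <- numeric(nlev)
  agg <- rowsum(x, g)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

subset_spots <- function(spots, keep) {
  spot_set(spots$positions[keep, , drop = FALSE],
           intensity = spots$intensity[keep], size = spots$size[keep],
           channel_id = spots$channel_id)
}
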