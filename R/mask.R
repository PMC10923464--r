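# Cell-mask extraction from a counterstain channel (e.g. a MAP2 or
# membrane stain) by K-class intensity K-means thresholding with a
# component-size filter and morphological closing.

#' Mask-segmentation parameters
#'
#' @param n_classes number of intensity classes K (2..10, default 3).
#' @param foreground_classes how many of the top classes count as
#'   foreground (default `n_classes - 1`).
#' @param min_size_px,max_size_px connected-component size bounds in
#'   voxels (defaults 50 and Inf).
#' @param dilation_px radius of the morphological closing applied to the
#'   filtered mask (default 2 px).
#' @return An `hk_params` list.
#' @export
hk_params <- function(n_classes = 3, foreground_classes = n_classes - 1,
                      min_size_px = 50, max_size_px = Inf,
                      dilation_px = 2) {
  stopifnot(n_classes >= 2, n_classes <= 10,
            foreground_classes >= 1, foreground_classes < n_classes,
            min_size_px >= 0, max_size_px >= min_size_px, dilation_px >= 0)
  structure(list(n_classes = as.integer(n_classes),
                 foreground_classes = as.integer(foreground_classes),
                 min_size_px = min_size_px, max_size_px = max_size_px,
                 dilation_px = as.integer(dilation_px)),
            class = "hk_params")
}

#' K-means intensity thresholds
#'
#' Runs 1D Lloyd K-means on the 256-bin intensity histogram over
#' `[min, max]`, with deterministic initialisation at equally spaced
#' quantiles, and returns the K-1 class boundaries (midpoints between
#' adjacent sorted centroids). Deterministic, and covariant under affine
#' intensity rescaling.
#'
#' @param channel numeric array with at least K distinct values.
#' @param K class count.
#' @param iter_max,tol Lloyd iteration cap and centroid-motion tolerance.
#' @return increasing numeric vector of K-1 thresholds.
#' @export
kmeans_intensity_thresholds <- function(channel, K, iter_max = 100,
                                        tol = 1e-6) {
  v <- as.numeric(channel)
  if (length(unique(v)) < K) stop("degenerate histogram")
  rng <- range(v)
  nb <- 256L
  br <- seq(rng[1], rng[2], length.out = nb + 1)
  bin <- pmin(pmax(findInterval(v, br, rightmost.closed = TRUE), 1L), nb)
  w <- tabulate(bin, nb)
  centers_bin <- (br[-1] + br[-(nb + 1)]) / 2
  # init at equally spaced quantiles of the histogram CDF
  cdf <- cumsum(w) / sum(w)
  init_q <- (2 * seq_len(K) - 1) / (2 * K)
  cent <- centers_bin[vapply(init_q, function(q) which(cdf >= q)[1], 1L)]
  cent <- sort(cent)
  # collapse accidental duplicate initial centers
  if (anyDuplicated(cent))
    cent <- seq(rng[1], rng[2], length.out = K + 2)[2:(K + 1)]
  scale <- diff(rng)
  for (it in seq_len(iter_max)) {
    bounds <- (head(cent, -1) + cent[-1]) / 2
    assign <- findInterval(centers_bin, bounds) + 1
    new_cent <- cent
    for (k in seq_len(K)) {
      wk <- w[assign == k]
      if (sum(wk) > 0)
        new_cent[k] <- sum(wk * centers_bin[assign == k]) / sum(wk)
    }
    new_cent <- sort(new_cent)
    moved <- max(abs(new_cent - cent)) / max(scale, .Machine$double.eps)
    cent <- new_cent
    if (moved < tol) break
  }
  (head(cent, -1) + cent[-1]) / 2
}

#' Segment the cell mask from a counterstain channel
#'
#' Voxels brighter than the `(K - foreground_classes)`-th K-means
#' threshold are foreground; connected components outside the size bounds
#' are removed; the survivors are closed with a ball of radius
#' `dilation_px`.
#'
#' @param channel numeric matrix or 3D array.
#' @param params an [hk_params()] list.
#' @param pixel_size nm per pixel.
#' @param sweep_k optional increasing vector of K values: the smallest K
#'   whose largest surviving component lies inside the size bounds is
#'   used (the hierarchical variant); `NULL` uses `params$n_classes`.
#' @return A [cell_mask()].
#' @export
segment_cell_mask <- function(channel, params = hk_params(),
                              pixel_size = 100, sweep_k = NULL) {
  d <- length(dim(channel))
  ps <- check_pixel_size(pixel_size, d)
  ks <- if (is.null(sweep_k)) params$n_classes else sort(unique(sweep_k))
  sweep <- !is.null(sweep_k)
  last_err <- NULL
  for (K in ks) {
    fg_classes <- min(params$foreground_classes, K - 1)
    grid <- try(segment_once(channel, K, fg_classes, params,
                             require_largest_in_bounds = sweep),
                silent = TRUE)
    if (inherits(grid, "try-error")) {
      last_err <- attr(grid, "condition")
      next
    }
    return(cell_mask(grid, ps))
  }
  stop(if (!is.null(last_err)) conditionMessage(last_err) else "no cell found")
}

segment_once <- function(channel, K, fg_classes, params,
                         require_largest_in_bounds = FALSE) {
  th <- kmeans_intensity_thresholds(channel, K)
  fg <- channel > th[K - fg_classes]
  dim(fg) <- dim(channel)
  lab <- label_components(fg)
  nlab <- max(lab)
  if (nlab == 0) stop("no cell found")
  sizes <- tabulate(lab[lab > 0], nlab)
  if (require_largest_in_bounds &&
      (max(sizes) < params$min_size_px || max(sizes) > params$max_size_px))
    stop("no cell found")
  ok <- which(sizes >= params$min_size_px & sizes <= params$max_size_px)
  if (length(ok) == 0) stop("no cell found")
  keep <- array(lab %in% ok, dim(channel))
  binary_close(keep, params$dilation_px)
}
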