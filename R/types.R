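# Shared domain types. All positions are continuous physical coordinates in
# nanometres with the origin at the outer corner of pixel (0,0): the centre
# of 0-based pixel (i,j) sits at ((j+0.5)*ps_x, (i+0.5)*ps_y). Grids are R
# arrays with dim (y, x[, z]) so that printed matrices match image layout.

#' Multichannel image stack
#'
#' Container for a 2D or 3D fluorescence image: a list of per-channel
#' arrays sharing one geometry, plus the physical pixel size.
#'
#' @param channels list of numeric arrays, one per channel, each with dim
#'   `(y, x)` or `(y, x, z)`; all identical.
#' @param pixel_size numeric vector of nm per pixel, named `x`, `y`
#'   (and `z` for 3D stacks).
#' @param channel_names optional character labels, one per channel.
#' @return An `image_stack` object.
#' @export
image_stack <- function(channels, pixel_size, channel_names = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1)
  d <- dim(channels[[1]])
  if (is.null(d)) stop("channels must be matrices or 3D arrays")
  if (!length(d) %in% c(2L, 3L)) stop("channels must be 2D or 3D")
  for (ch in channels) {
    if (!identical(dim(ch), d)) stop("all channels must share one geometry")
    if (!is.numeric(ch)) stop("non-numeric pixel data")
  }
  ps <- check_pixel_size(pixel_size, length(d))
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_along(channels))
  stopifnot(length(channel_names) == length(channels))
  names(channels) <- channel_names
  structure(list(channels = channels, pixel_size = ps,
                 channel_names = channel_names,
                 dim = length(d), shape = d),
            class = "image_stack")
}

check_pixel_size <- function(pixel_size, d) {
  axes <- c("x", "y", "z")[seq_len(d)]
  if (is.null(names(pixel_size)))
    names(pixel_size) <- axes[seq_along(pixel_size)]
  if (length(pixel_size) == 1) {
    pixel_size <- rep(pixel_size, d)
    names(pixel_size) <- axes
  }
  if (!all(axes %in% names(pixel_size)))
    stop("pixel_size must name axes ", paste(axes, collapse = ", "))
  ps <- as.numeric(pixel_size[axes])
  names(ps) <- axes
  if (any(!is.finite(ps)) || any(ps <= 0)) stop("pixel_size must be > 0")
  ps
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image_stack: %d channel(s) [%s], %s px, pixel %s nm\n",
              length(x$channels), paste(x$channel_names, collapse = ", "),
              paste(rev(x$shape), collapse = " x "),
              paste(signif(x$pixel_size, 4), collapse = " x ")))
  invisible(x)
}

#' Point pattern of detected spots or localizations
#'
#' Positions are physical nm coordinates; marks carry per-spot total
#' intensity (a.u.) and size (pixel count; 1 for SMLM localizations).
#'
#' @param positions numeric matrix, one row per spot, columns `x`, `y`
#'   (and `z`), in nm.
#' @param intensity,size per-spot marks, recycled if scalar.
#' @param channel_id label of the source channel.
#' @return A `spot_set` object with fields `positions`, `intensity`,
#'   `size`, `channel_id`, `n`, `dim`.
#' @export
spot_set <- function(positions, intensity = 1, size = 1,
                     channel_id = "ch") {
  positions <- as.matrix(positions)
  if (nrow(positions) > 0 && !all(is.finite(positions)))
    stop("all coordinates must be finite")
  d <- ncol(positions)
  if (nrow(positions) == 0 && d == 0) {
    positions <- matrix(numeric(0), 0, 2)
    d <- 2L
  }
  if (!d %in% c(2L, 3L)) stop("positions must have 2 or 3 columns")
  colnames(positions) <- c("x", "y", "z")[seq_len(d)]
  n <- nrow(positions)
  structure(list(positions = positions,
                 intensity = rep_len(as.numeric(intensity), n),
                 size = rep_len(as.numeric(size), n),
                 channel_id = channel_id, n = n, dim = d),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("spot_set '%s': %d spot(s), %dD\n", x$channel_id, x$n, x$dim))
  invisible(x)
}

#' Binary cell mask
#'
#' Occupancy grid delimiting the analysis region. The measure |Omega| is
#' the occupied voxel count times the voxel measure (nm^2 or nm^3) and is
#' exact by construction.
#'
#' @param grid logical array with dim `(y, x[, z])`.
#' @param pixel_size nm per pixel (named `x`, `y` and optionally `z`, or
#'   a scalar).
#' @return A `cell_mask` object with fields `grid`, `pixel_size`,
#'   `measure`, `dim`.
#' @export
cell_mask <- function(grid, pixel_size) {
  if (is.numeric(grid)) {
    dd <- dim(grid)
    grid <- grid > 0
    dim(grid) <- dd
  }
  if (!is.logical(grid) || is.null(dim(grid)))
    stop("grid must be a logical array")
  d <- length(dim(grid))
  if (!d %in% c(2L, 3L)) stop("grid must be 2D or 3D")
  ps <- check_pixel_size(pixel_size, d)
  measure <- sum(grid) * prod(ps)
  if (measure <= 0) stop("mask measure must be > 0 (empty mask)")
  structure(list(grid = grid, pixel_size = ps, measure = measure, dim = d),
            class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  unit <- if (x$dim == 2) "nm^2" else "nm^3"
  cat(sprintf("cell_mask: %s px, %d occupied, |Omega| = %.4g %s\n",
              paste(rev(dim(x$grid)), collapse = " x "), sum(x$grid),
              x$measure, unit))
  invisible(x)
}

#' Concentric distance rings
#'
#' Strictly increasing ring boundaries `0 = r_0 < r_1 < ... < r_K` (nm).
#' Pair distances are binned half-open: ring k holds `r_{k-1} <= d < r_k`,
#' so a distance exactly on a boundary falls in the outer ring.
#'
#' @param radii increasing numeric vector starting at 0.
#' @return A `ring_spec` with fields `radii`, `K`.
#' @export
ring_spec <- function(radii) {
  radii <- as.numeric(radii)
  if (radii[1] != 0) stop("radii must start at r_0 = 0")
  if (length(radii) < 2 || any(diff(radii) <= 0))
    stop("radii must be strictly increasing with K >= 1 rings")
  structure(list(radii = radii, K = length(radii) - 1L), class = "ring_spec")
}

#' Uniform-width rings up to a maximum radius
#'
#' @param r_max outer radius in nm (default 300, the single-molecule
#'   regime default).
#' @param width ring width in nm (default 30).
#' @return A `ring_spec`.
#' @export
rings_uniform <- function(r_max = 300, width = 30) {
  ring_spec(seq(0, r_max, by = width))
}

# ---- coordinate helpers ------------------------------------------------

# nm positions (matrix cols x,y[,z]) -> 1-based grid indices (row, col[, slice])
nm_to_index <- function(positions, pixel_size) {
  positions <- as.matrix(positions)
  d <- ncol(positions)
  idx <- cbind(row = floor(positions[, 2] / pixel_size["y"]) + 1,
               col = floor(positions[, 1] / pixel_size["x"]) + 1)
  if (d == 3)
    idx <- cbind(idx, slice = floor(positions[, 3] / pixel_size["z"]) + 1)
  storage.mode(idx) <- "integer"
  idx
}

# 1-based grid indices -> nm coordinates of voxel centres
index_to_nm <- function(idx, pixel_size) {
  idx <- as.matrix(idx)
  pos <- cbind(x = (idx[, 2] - 0.5) * pixel_size["x"],
               y = (idx[, 1] - 0.5) * pixel_size["y"])
  if (ncol(idx) == 3)
    pos <- cbind(pos, z = (idx[, 3] - 0.5) * pixel_size["z"])
  pos
}

# vectorized membership of nm positions in a cell_mask
mask_contains <- function(mask, positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) == 0) return(logical(0))
  if (ncol(positions) != mask$dim)
    stop("dimension mismatch between mask and positions")
  idx <- nm_to_index(positions, mask$pixel_size)
  dm <- dim(mask$grid)
  ok <- idx[, 1] >= 1 & idx[, 1] <= dm[1] & idx[, 2] >= 1 & idx[, 2] <= dm[2]
  if (mask$dim == 3) ok <- ok & idx[, 3] >= 1 & idx[, 3] <= dm[3]
  out <- logical(nrow(positions))
  if (any(ok)) out[ok] <- mask$grid[idx[ok, , drop = FALSE]]
  out
}

# uniform points inside the mask: uniform occupied voxel + uniform offset
sample_in_mask <- function(mask, n) {
  occ <- which(mask$grid)
  if (length(occ) == 0) stop("mask too small to place points")
  pick <- occ[sample.int(length(occ), n, replace = TRUE)]
  idx <- arrayInd(pick, dim(mask$grid))
  ps <- mask$pixel_size
  pos <- cbind(x = (idx[, 2] - 1 + runif(n)) * ps["x"],
               y = (idx[, 1] - 1 + runif(n)) * ps["y"])
  if (mask$dim == 3)
    pos <- cbind(pos, z = (idx[, 3] - 1 + runif(n)) * ps["z"])
  rownames(pos) <- NULL
  pos
}
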