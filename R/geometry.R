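# Binary morphology and connected components on (y, x[, z]) logical arrays.
# Implemented dimension-generically so the same code serves 2D images and
# 3D stacks; structuring element is the Euclidean ball of integer radius r.

ball_offsets <- function(r, d) {
  ax <- -r:r
  g <- as.matrix(do.call(expand.grid, rep(list(ax), d)))
  g[rowSums(g^2) <= r^2, , drop = FALSE]
}

# grid translated by `off` (row, col[, slice]); cells shifted in from
# outside take `fill`
offset_view <- function(a, off, fill = FALSE) {
  d <- dim(a)
  src <- vector("list", length(d))
  dst <- vector("list", length(d))
  for (k in seq_along(d)) {
    s <- seq_len(d[k]) - off[k]
    keep <- s >= 1 & s <= d[k]
    src[[k]] <- s[keep]
    dst[[k]] <- which(keep)
  }
  out <- array(fill, d)
  if (any(vapply(src, length, 1L) == 0)) return(out)
  out[make_slice_index(dst, d)] <- a[make_slice_index(src, d)]
  out
}

make_slice_index <- function(ix, d) {
  # linear indices of the cartesian product of per-axis index vectors
  if (length(d) == 2) {
    as.vector(outer(ix[[1]], (ix[[2]] - 1) * d[1], `+`))
  } else {
    p <- outer(ix[[1]], (ix[[2]] - 1) * d[1], `+`)
    as.vector(outer(as.vector(p), (ix[[3]] - 1) * d[1] * d[2], `+`))
  }
}

binary_dilate <- function(grid, r) {
  if (r <= 0) return(grid)
  offs <- ball_offsets(r, length(dim(grid)))
  out <- array(FALSE, dim(grid))
  for (k in seq_len(nrow(offs)))
    out <- out | offset_view(grid, offs[k, ], fill = FALSE)
  out
}

binary_erode <- function(grid, r) {
  if (r <= 0) return(grid)
  offs <- ball_offsets(r, length(dim(grid)))
  out <- array(TRUE, dim(grid))
  for (k in seq_len(nrow(offs)))
    out <- out & offset_view(grid, offs[k, ], fill = FALSE)
  out
}

binary_close <- function(grid, r) binary_erode(binary_dilate(grid, r), r)

# connected components with full (8 / 26) connectivity; returns an integer
# array of labels, 0 = background
label_components <- function(keep) {
  d <- dim(keep)
  cpp_label_components(as.logical(keep), as.integer(d))
}
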