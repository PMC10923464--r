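# Image and localization-table IO plus the exported artifacts: results
# CSVs and the color-coded molecular association map.
#
# TIFF dialect: multi-page, one page per channel (2D) or channel-major
# Z-pages (3D: all slices of ch1, then ch2, ...). Integer data are stored
# as 16-bit and round-trip bit-exactly; pixel size is supplied by the
# caller/config (nm) since fixtures carry no calibrated metadata.

#' Read a multichannel TIFF into an image stack
#'
#' @param path TIFF file.
#' @param n_channels number of channels encoded in the page sequence;
#'   pages are split channel-major, so `pages / n_channels` Z-slices per
#'   channel (1 for 2D).
#' @param pixel_size nm per pixel (scalar or named per axis); TIFF
#'   metadata is not consulted.
#' @param channel_names optional labels, length `n_channels`.
#' @return An [image_stack()]; 3D when more than one Z-slice per channel.
#' @export
read_image <- function(path, n_channels = NULL, pixel_size = 100,
                       channel_names = NULL) {
  if (!file.exists(path)) stop("missing file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1] # collapse stored RGB planes
    if (!is.numeric(p)) stop("non-numeric pixel data")
    p
  })
  np <- length(pages)
  if (is.null(n_channels)) n_channels <- np
  if (np %% n_channels != 0)
    stop("page count ", np, " not divisible by n_channels ", n_channels)
  nz <- np %/% n_channels
  channels <- lapply(seq_len(n_channels), function(ci) {
    zs <- pages[((ci - 1) * nz + 1):(ci * nz)]
    if (nz == 1) zs[[1]] else array(unlist(zs), c(dim(zs[[1]]), nz))
  })
  image_stack(channels, pixel_size = pixel_size,
              channel_names = channel_names)
}

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' @param img an [image_stack()]; values must be nonnegative integers
#'   below 2^16 (photon counts).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  pages <- list()
  for (ch in img$channels) {
    if (any(ch < 0) || any(ch >= 65536) || any(ch != round(ch)))
      stop("write_image stores 16-bit integer counts (0..65535)")
    if (img$dim == 2) {
      pages <- c(pages, list(ch / 65535))
    } else {
      pages <- c(pages, lapply(seq_len(dim(ch)[3]),
                               function(z) ch[, , z] / 65535))
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Select one channel of an image stack by index or name
#' @param img an [image_stack()].
#' @param channel integer index or channel name.
#' @return the channel's numeric array.
#' @export
get_channel <- function(img, channel) {
  if (is.character(channel)) {
    if (!channel %in% img$channel_names)
      stop("unknown channel '", channel, "'")
    return(img$channels[[channel]])
  }
  channel <- as.integer(channel)
  if (channel < 1 || channel > length(img$channels))
    stop("channel index ", channel, " out of range (",
         length(img$channels), " channels)")
  img$channels[[channel]]
}

write_mask <- function(mask, path) {
  g <- mask$grid * 1
  dim(g) <- dim(mask$grid)
  write_image(image_stack(list(mask = g), pixel_size = mask$pixel_size),
              path)
}

read_mask <- function(path, pixel_size = 100) {
  img <- read_image(path, n_channels = 1, pixel_size = pixel_size)
  cell_mask(img$channels[[1]] > 0, img$pixel_size)
}

#' Read a localization table (CSV) into spot sets
#'
#' Comma-separated with a header. Column names are resolved through
#' `column_map`; by default `x`/`y`/`z` and the ThunderSTORM-style
#' `x [nm]` variants are accepted. Rows with non-finite coordinates are
#' dropped with a message stating the count. Coordinates declared in
#' pixel units are converted using `pixel_size`.
#'
#' @param path CSV file.
#' @param column_map named list/vector mapping roles `x`, `y`, `z`,
#'   `channel`, `intensity` to column names (`z`, `channel`, `intensity`
#'   optional).
#' @param unit `"nm"` (default) or `"px"`.
#' @param pixel_size nm per pixel, used when `unit = "px"`.
#' @return A [spot_set()] when the table holds one channel, otherwise a
#'   named list of [spot_set()]s split by the channel column.
#' @export
read_localizations <- function(path, column_map = NULL, unit = c("nm", "px"),
                               pixel_size = 100) {
  if (!file.exists(path)) stop("missing file: ", path)
  unit <- match.arg(unit)
  tab <- read.csv(path, check.names = FALSE)
  find_col <- function(role, aliases, required) {
    nm <- if (!is.null(column_map) && role %in% names(column_map))
      column_map[[role]] else intersect(aliases, names(tab))[1]
    if (is.null(nm) || is.na(nm)) {
      if (required) stop("missing mandatory column for '", role, "'")
      return(NULL)
    }
    if (!nm %in% names(tab))
      stop("missing mandatory column '", nm, "'")
    nm
  }
  cx <- find_col("x", c("x", "x [nm]", "x_nm"), TRUE)
  cy <- find_col("y", c("y", "y [nm]", "y_nm"), TRUE)
  cz <- find_col("z", c("z", "z [nm]", "z_nm"), FALSE)
  cch <- find_col("channel", c("channel", "ch"), FALSE)
  cint <- find_col("intensity", c("intensity", "photons"), FALSE)
  pos <- cbind(x = as.numeric(tab[[cx]]), y = as.numeric(tab[[cy]]))
  if (!is.null(cz)) pos <- cbind(pos, z = as.numeric(tab[[cz]]))
  ok <- rowSums(!is.finite(pos)) == 0
  if (any(!ok))
    message("read_localizations: dropped ", sum(!ok),
            " row(s) with non-finite coordinates")
  pos <- pos[ok, , drop = FALSE]
  if (unit == "px") {
    ps <- check_pixel_size(pixel_size, ncol(pos))
    pos <- sweep(pos, 2, ps[colnames(pos)], `*`)
  }
  intens <- if (!is.null(cint)) as.numeric(tab[[cint]])[ok] else 1
  if (is.null(cch)) {
    return(spot_set(pos, intensity = intens, size = 1,
                    channel_id = tools::file_path_sans_ext(basename(path))))
  }
  chv <- tab[[cch]][ok]
  out <- lapply(split(seq_len(nrow(pos)), chv), function(ix)
    spot_set(pos[ix, , drop = FALSE],
             intensity = if (length(intens) > 1) intens[ix] else intens,
             size = 1, channel_id = as.character(chv[ix[1]])))
  out
}

#' Write a spot set as a localization CSV
#' @param spots a [spot_set()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(spots, path) {
  df <- as.data.frame(spots$positions)
  df$intensity <- spots$intensity
  df$size <- spots$size
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# fixed results schema; order is part of the contract
RESULTS_COLUMNS <- c("input", "channel_pair", "dim", "N1", "N2", "n_pairs",
                     "n_coupled", "coupling_fraction_ch1",
                     "coupling_fraction_ch2", "mean_coupling_distance_nm",
                     "sd_coupling_distance_nm", "p_value", "alpha",
                     "n_rings", "r_max_nm", "mask_measure", "seed",
                     "status")

#' One results-table row from a coupling analysis
#'
#' @param input input identifier (file name or scenario id).
#' @param profile,coupling outputs of [run_soda()].
#' @param seed seed used for the null resamples.
#' @param channel_pair label such as `"ch1->ch2"`.
#' @param status `"ok"` or an error note (batch mode flags failures).
#' @return one-row data.frame with the documented column order.
#' @export
results_row <- function(input, profile, coupling, seed = NA,
                        channel_pair = "ch1->ch2", status = "ok") {
  data.frame(input = input, channel_pair = channel_pair,
             dim = profile$dim, N1 = profile$n1, N2 = profile$n2,
             n_pairs = nrow(profile$pairs),
             n_coupled = coupling$n_coupled,
             coupling_fraction_ch1 = coupling$coupling_fraction_ch1,
             coupling_fraction_ch2 = coupling$coupling_fraction_ch2,
             mean_coupling_distance_nm = coupling$mu_d,
             sd_coupling_distance_nm = coupling$sd_d,
             p_value = coupling$p_value, alpha = coupling$alpha,
             n_rings = profile$rings$K,
             r_max_nm = max(profile$rings$radii),
             mask_measure = NA_real_, seed = seed, status = status,
             stringsAsFactors = FALSE)
}

#' Per-ring diagnostics table
#' @param profile,coupling outputs of [run_soda()].
#' @return data.frame with one row per ring.
#' @export
ring_table <- function(profile, coupling) {
  r <- profile$rings$radii
  data.frame(ring = seq_len(profile$rings$K),
             r_inner_nm = r[-length(r)], r_outer_nm = r[-1],
             n_pairs = tabulate(profile$pairs$ring, profile$rings$K),
             K_hat = profile$K_hat, A = profile$A,
             sigma = coupling$sigma, z = coupling$z,
             p_ring = coupling$p_ring)
}

#' Write result tables to disk
#'
#' Writes one CSV per table (named from its `input` column) plus the
#' concatenated `soda_results_batch.csv`, always with the documented
#' column order; numeric values round-trip to at least 12 significant
#' digits.
#'
#' @param tables list of one-row (or multi-row) results data.frames.
#' @param out_dir output directory (created if needed).
#' @return character vector of written file paths, invisibly.
#' @export
write_results <- function(tables, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("unwritable directory: ", out_dir)
  written <- character(0)
  for (tab in tables) {
    f <- file.path(out_dir, paste0(
      gsub("[^A-Za-z0-9_.-]", "_", tab$input[1]), "_results.csv"))
    write.csv(tab[, RESULTS_COLUMNS], f, row.names = FALSE)
    written <- c(written, f)
  }
  batch <- if (length(tables)) do.call(rbind, lapply(tables, `[`,
                                                     RESULTS_COLUMNS))
    else empty_results_table()
  bf <- file.path(out_dir, "soda_results_batch.csv")
  write.csv(batch, bf, row.names = FALSE)
  invisible(c(written, bf))
}

empty_results_table <- function() {
  df <- as.data.frame(setNames(rep(list(character(0)),
                                   length(RESULTS_COLUMNS)),
                               RESULTS_COLUMNS))
  df
}

# the five documented map colors (+ black background), fixed RGB
SODA_COLORS <- list(background = c(0, 0, 0),
                    mask = c(0, 0, 139) / 255,      # deep blue
                    ch1_isolated = c(0, 1, 0),       # green
                    ch1_associated = c(0, 1, 1),     # cyan
                    ch2_isolated = c(1, 0, 0),       # red
                    ch2_associated = c(1, 105 / 255, 180 / 255)) # pink

#' Render the color-coded molecular association map
#'
#' The mask is painted deep blue; channel-1 spots are green when
#' isolated and cyan when associated; channel-2 spots are red when
#' isolated and pink when associated (association flag: per-spot
#' probability > 0.5). Deterministic given its inputs; only the five
#' documented colors plus the black background appear.
#'
#' @param spots1,spots2 the analysed [spot_set()]s.
#' @param coupling the [coupling_probabilities()] result computed from
#'   them.
#' @param mask the 2D [cell_mask()] used in the analysis.
#' @param path optional PNG output file.
#' @param spot_radius_px painted disc radius (default 2).
#' @return the H x W x 3 RGB array, invisibly.
#' @export
render_molecular_map <- function(spots1, spots2, coupling, mask,
                                 path = NULL, spot_radius_px = 2) {
  if (mask$dim != 2) stop("molecular maps are rendered in 2D")
  if (spots1$dim != 2 || spots2$dim != 2)
    stop("dimension mismatch between mask and spots")
  if (length(coupling$associated_ch1) != spots1$n ||
      length(coupling$associated_ch2) != spots2$n)
    stop("coupling result does not match the spot sets")
  dm <- dim(mask$grid)
  rgb <- array(0, c(dm, 3))
  for (b in 1:3)
    rgb[, , b][mask$grid] <- SODA_COLORS$mask[b]
  rgb <- paint_spots(rgb, mask, spots1, coupling$associated_ch1,
                     SODA_COLORS$ch1_isolated, SODA_COLORS$ch1_associated,
                     spot_radius_px)
  rgb <- paint_spots(rgb, mask, spots2, coupling$associated_ch2,
                     SODA_COLORS$ch2_isolated, SODA_COLORS$ch2_associated,
                     spot_radius_px)
  if (!is.null(path)) png::writePNG(rgb, path)
  invisible(rgb)
}

paint_spots <- function(rgb, mask, spots, assoc, col_iso, col_assoc, r) {
  if (spots$n == 0) return(rgb)
  dm <- dim(mask$grid)
  offs <- ball_offsets(r, 2)
  idx <- nm_to_index(spots$positions, mask$pixel_size)
  for (k in seq_len(spots$n)) {
    px <- cbind(idx[k, 1] + offs[, 1], idx[k, 2] + offs[, 2])
    px <- px[px[, 1] >= 1 & px[, 1] <= dm[1] &
               px[, 2] >= 1 & px[, 2] <= dm[2], , drop = FALSE]
    col <- if (isTRUE(assoc[k])) col_assoc else col_iso
    for (b in 1:3)
      rgb[cbind(px, b)] <- col[b]
  }
  rgb
}
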