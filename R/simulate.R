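# Synthetic ground-truth generator: a cell-shaped binary mask, two point
# populations with a known coupled fraction at a known coupling distance
# (with jitter), and optional Gaussian-PSF + Poisson-noise image
# rendering. Stands in for two-protein neuronal images in every test.
#
# Default study conditions: a 10 x 10 um field at 100 nm pixels, 300
# points per channel, coupling distance 50 nm with 10 nm jitter, and
# rendering at peak SNR ~ 9 (photon_scale 2000 over background 2).

#' Simulation scenario
#'
#' @param mask_shape `"rectangle"` (whole field), `"disk"` (inset disk,
#'   radius 0.45 of the short side), or `"neurite"` (random-walk skeleton
#'   dilated to a thin process).
#' @param nx,ny,nz grid size in pixels (`nz = 1` for 2D).
#' @param pixel_size nm per pixel (scalar or named per axis).
#' @param N1,N2 channel point counts.
#' @param coupled_fraction fraction q of channel-2 points tied to a
#'   channel-1 partner.
#' @param coupling_distance nominal partner distance d_c (nm).
#' @param jitter_sd sd of the Gaussian jitter on the partner distance
#'   (nm); the realised distance is `|N(d_c, jitter_sd^2)|`.
#' @param min_separation optional hard-core radius (nm) enforced within
#'   each channel's uniform points (0 disables; used by detection
#'   benchmarks so spots stay resolvable).
#' @param psf_sigma_px,photon_scale,background_rate image rendering: PSF
#'   sigma in px, photons per unit mark, and uniform Poisson background
#'   rate per pixel.
#' @param neurite_steps,neurite_radius_px random-walk length and dilation
#'   radius of the neurite mask.
#' @param seed integer RNG seed (every generator call is deterministic
#'   given the scenario).
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(mask_shape = c("rectangle", "disk", "neurite"),
                         nx = 100, ny = 100, nz = 1, pixel_size = 100,
                         N1 = 300, N2 = 300, coupled_fraction = 0.3,
                         coupling_distance = 50, jitter_sd = 10,
                         min_separation = 0, psf_sigma_px = 2,
                         photon_scale = 2000, background_rate = 2,
                         neurite_steps = 500, neurite_radius_px = 4,
                         seed = 1) {
  mask_shape <- match.arg(mask_shape)
  stopifnot(coupled_fraction >= 0, coupled_fraction <= 1,
            coupling_distance >= 0, jitter_sd >= 0, N1 >= 0, N2 >= 0,
            nx >= 1, ny >= 1, nz >= 1)
  structure(list(mask_shape = mask_shape, nx = as.integer(nx),
                 ny = as.integer(ny), nz = as.integer(nz),
                 pixel_size = pixel_size, N1 = as.integer(N1),
                 N2 = as.integer(N2), coupled_fraction = coupled_fraction,
                 coupling_distance = coupling_distance,
                 jitter_sd = jitter_sd, min_separation = min_separation,
                 psf_sigma_px = psf_sigma_px, photon_scale = photon_scale,
                 background_rate = background_rate,
                 neurite_steps = as.integer(neurite_steps),
                 neurite_radius_px = as.integer(neurite_radius_px),
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

scenario_mask <- function(sc) {
  d <- if (sc$nz > 1) 3L else 2L
  dm <- if (d == 3) c(sc$ny, sc$nx, sc$nz) else c(sc$ny, sc$nx)
  ps <- check_pixel_size(sc$pixel_size, d)
  grid <- switch(sc$mask_shape,
    rectangle = array(TRUE, dm),
    disk = {
      r <- 0.45 * min(sc$nx, sc$ny)
      cy <- sc$ny / 2 + 0.5
      cx <- sc$nx / 2 + 0.5
      g <- outer(seq_len(sc$ny) - cy, seq_len(sc$nx) - cx,
                 function(a, b) a^2 + b^2 <= r^2)
      if (d == 3) array(rep(g, sc$nz), dm) else g
    },
    neurite = {
      g <- array(FALSE, c(sc$ny, sc$nx))
      r <- c(sc$ny %/% 2, sc$nx %/% 2)
      for (s in seq_len(sc$neurite_steps)) {
        g[r[1], r[2]] <- TRUE
        step <- sample(4, 1)
        r <- r + switch(step, c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
        r <- pmin(pmax(r, 1), c(sc$ny, sc$nx))
      }
      g <- binary_dilate(g, sc$neurite_radius_px)
      if (d == 3) array(rep(g, sc$nz), dm) else g
    })
  cell_mask(grid, ps)
}

#' Simulate ground-truth point patterns with known coupling
#'
#' Channel 1 is uniform inside the mask. `round(q * N2)` channel-2 points
#' sit at distance `|N(d_c, sigma_c^2)|` from a uniformly chosen
#' channel-1 partner in a uniform direction (the direction is resampled
#' until the point lands inside the mask, preserving the distance law);
#' the rest are uniform. The RNG is consumed identically for every value
#' of q, so patterns at increasing q are nested (the same points turn
#' coupled).
#'
#' @param sc a [sim_scenario()].
#' @return list with `mask` ([cell_mask()]), `spots1`, `spots2`
#'   ([spot_set()]s) and `truth` (data.frame: `j`, `partner` (NA when
#'   uncoupled), `d_true` nm).
#' @export
simulate_patterns <- function(sc) {
  n_coupled <- round(sc$coupled_fraction * sc$N2)
  if (n_coupled > 0 && sc$N1 == 0)
    stop("cannot couple channel-2 points: N1 = 0")
  with_seed(sc$seed, {
    mask <- scenario_mask(sc)
    d <- mask$dim
    pos1 <- sample_hardcore(mask, sc$N1, sc$min_separation)
    pos2 <- matrix(NA_real_, sc$N2, d)
    partner <- rep(NA_integer_, sc$N2)
    d_true <- rep(NA_real_, sc$N2)
    unif2 <- sample_hardcore(mask, sc$N2, sc$min_separation)
    for (j in seq_len(sc$N2)) {
      # draw the coupled candidate for every j regardless of q (keeps the
      # stream aligned across q); use it only for the first n_coupled
      cand <- draw_coupled_point(pos1, mask, sc$coupling_distance,
                                 sc$jitter_sd)
      if (j <= n_coupled) {
        pos2[j, ] <- cand$pos
        partner[j] <- cand$partner
        d_true[j] <- cand$d
      } else {
        pos2[j, ] <- unif2[j, ]
      }
    }
    colnames(pos2) <- c("x", "y", "z")[seq_len(d)]
    list(mask = mask,
         spots1 = spot_set(pos1, channel_id = "ch1"),
         spots2 = spot_set(pos2, channel_id = "ch2"),
         truth = data.frame(j = seq_len(sc$N2), partner = partner,
                            d_true = d_true))
  })
}

sample_hardcore <- function(mask, n, min_sep) {
  pos <- sample_in_mask(mask, n)
  if (min_sep <= 0 || n < 2) return(pos)
  for (i in 2:n) {
    tries <- 0
    repeat {
      dd <- sqrt(rowSums((pos[seq_len(i - 1), , drop = FALSE] -
                            matrix(pos[i, ], i - 1, ncol(pos),
                                   byrow = TRUE))^2))
      if (min(dd) >= min_sep || tries >= 200) break
      pos[i, ] <- sample_in_mask(mask, 1)
      tries <- tries + 1
    }
  }
  pos
}

draw_coupled_point <- function(pos1, mask, d_c, sigma_c) {
  n1 <- nrow(pos1)
  partner <- sample.int(n1, 1)
  dist <- abs(rnorm(1, d_c, sigma_c))
  d <- ncol(pos1)
  for (try in seq_len(400)) {
    u <- rnorm(d)
    u <- u / sqrt(sum(u^2))
    p <- pos1[partner, ] + dist * u
    if (mask_contains(mask, matrix(p, 1))) {
      return(list(pos = p, partner = partner, d = dist))
    }
    if (try %% 100 == 0) { # stuck partner: redraw partner and distance
      partner <- sample.int(n1, 1)
      dist <- abs(rnorm(1, d_c, sigma_c))
    }
  }
  list(pos = pos1[partner, ], partner = partner, d = 0)
}

#' Render a scenario as a noisy fluorescence image
#'
#' Each spot is splatted as an isotropic Gaussian of sigma
#' `psf_sigma_px` whose integral is `photon_scale * mark`; a uniform
#' Poisson background of rate `background_rate` is added and the whole
#' image is Poisson-sampled. A third channel renders the mask as a
#' counterstain (background 10, mask 200, Poisson-sampled) so the full
#' image pipeline can be exercised end to end.
#'
#' @param mask a 2D [cell_mask()].
#' @param spots1,spots2 [spot_set()]s to render.
#' @param sc the [sim_scenario()] carrying the rendering parameters.
#' @param seed optional override of `sc$seed` for the noise stream.
#' @return An [image_stack()] with channels `ch1`, `ch2`, `mask`.
#' @export
render_image <- function(mask, spots1, spots2, sc, seed = sc$seed) {
  if (mask$dim != 2) stop("image rendering is 2D only")
  ps <- mask$pixel_size
  dm <- dim(mask$grid)
  with_seed(seed, {
    lam1 <- splat_gaussian(dm, ps, spots1, sc$psf_sigma_px,
                           sc$photon_scale) + sc$background_rate
    lam2 <- splat_gaussian(dm, ps, spots2, sc$psf_sigma_px,
                           sc$photon_scale) + sc$background_rate
    ch1 <- array(rpois(length(lam1), lam1), dm)
    ch2 <- array(rpois(length(lam2), lam2), dm)
    stain <- array(rpois(length(mask$grid),
                         ifelse(mask$grid, 200, 10)), dm)
    image_stack(list(ch1 = ch1, ch2 = ch2, mask = stain), pixel_size = ps)
  })
}

splat_gaussian <- function(dm, ps, spots, sigma_px, photon_scale) {
  lam <- array(0, dm)
  if (spots$n == 0 || photon_scale <= 0) return(lam)
  half <- ceiling(4 * sigma_px)
  for (k in seq_len(spots$n)) {
    cx <- spots$positions[k, "x"] / ps["x"] # 0-based px coords
    cy <- spots$positions[k, "y"] / ps["y"]
    cols <- max(1, floor(cx) - half + 1):min(dm[2], floor(cx) + half + 1)
    rows <- max(1, floor(cy) - half + 1):min(dm[1], floor(cy) + half + 1)
    gx <- exp(-((cols - 0.5 - cx)^2) / (2 * sigma_px^2))
    gy <- exp(-((rows - 0.5 - cy)^2) / (2 * sigma_px^2))
    amp <- photon_scale * spots$size[k] / (2 * pi * sigma_px^2)
    lam[rows, cols] <- lam[rows, cols] + amp * outer(gy, gx)
  }
  lam
}

#' Write a folder of simulated fixtures
#'
#' For each scenario writes a rendered 3-channel TIFF, per-channel
#' localization CSVs, a truth CSV, a binary mask TIFF, and appends a row
#' to `manifest.csv`. Rerunning with the same scenarios reproduces the
#' CSVs byte-identically.
#'
#' @param scenarios list of [sim_scenario()]s.
#' @param out_dir output directory (created if needed).
#' @return the manifest data.frame (zero rows for an empty grid).
#' @export
simulate_batch <- function(scenarios, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("unwritable directory: ", out_dir)
  rows <- vector("list", length(scenarios))
  for (k in seq_along(scenarios)) {
    sc <- scenarios[[k]]
    id <- sprintf("sim%03d", k)
    pat <- simulate_patterns(sc)
    write_localizations(pat$spots1, file.path(out_dir, paste0(id, "_ch1.csv")))
    write_localizations(pat$spots2, file.path(out_dir, paste0(id, "_ch2.csv")))
    write.csv(pat$truth, file.path(out_dir, paste0(id, "_truth.csv")),
              row.names = FALSE)
    write_mask(pat$mask, file.path(out_dir, paste0(id, "_mask.tif")))
    img_file <- NA_character_
    if (pat$mask$dim == 2) {
      img <- render_image(pat$mask, pat$spots1, pat$spots2, sc)
      img_file <- paste0(id, ".tif")
      write_image(img, file.path(out_dir, img_file))
    }
    rows[[k]] <- data.frame(id = id, seed = sc$seed,
                            mask_shape = sc$mask_shape,
                            N1 = sc$N1, N2 = sc$N2,
                            coupled_fraction = sc$coupled_fraction,
                            coupling_distance = sc$coupling_distance,
                            jitter_sd = sc$jitter_sd,
                            image = img_file,
                            ch1 = paste0(id, "_ch1.csv"),
                            ch2 = paste0(id, "_ch2.csv"),
                            truth = paste0(id, "_truth.csv"),
                            mask = paste0(id, "_mask.tif"))
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), seed = integer(0),
               mask_shape = character(0), N1 = integer(0), N2 = integer(0),
               coupled_fraction = numeric(0), coupling_distance = numeric(0),
               jitter_sd = numeric(0), image = character(0),
               ch1 = character(0), ch2 = character(0), truth = character(0),
               mask = character(0))
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}
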