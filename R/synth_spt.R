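# Synthetic 3D single-particle-tracking data: fractional Brownian motion
# trajectories with a known (D, alpha), and rendering of trajectories into
# nine-plane multifocal camera movies with known plane misalignments and
# detection-efficiency factors.

#' Configuration for synthetic 3D tracking data
#'
#' Defaults follow the multifocal acquisition being emulated: 32 ms frames,
#' 30 s movies, nine focal planes with a nominal 400 nm axial separation and
#' per-plane detection efficiencies scattered within about +/-15% of their
#' mean, and ~20 nm localization noise.
#'
#' @param D_true Generalized diffusion coefficient (um^2/s^alpha).
#' @param alpha Anomalous exponent in (0, 2]; 1 = Brownian.
#' @param dt Frame interval (s).
#' @param n_frames Frames per movie (default 30 s / 32 ms).
#' @param n_particles Number of trajectories.
#' @param loc_sd Localization noise SD per coordinate (nm).
#' @param plane_spacing Axial separation between focal planes (nm).
#' @param plane_misalignments List of nine 2x3 affine matrices mapping
#'   reference-plane pixel coordinates to each tile's observed coordinates
#'   (NULL = identity for all planes).
#' @param plane_efficiencies Nine relative detection-efficiency factors
#'   (NULL = all 1). Must lie within \[0.70, 1.30\] of their mean.
#' @param efficiency_jitter If `plane_efficiencies` is NULL and this is > 0,
#'   efficiencies are drawn uniformly within +/- this fraction of 1.
#' @param tile_px Side of one focal-plane sub-image (pixels).
#' @param pixel_size Lateral pixel size (um/px).
#' @param psf_sigma_xy Lateral PSF Gaussian sigma (um).
#' @param psf_sigma_z Axial response sigma of one focal plane (nm).
#' @param spot_photons Expected photons per in-focus spot.
#' @param background_photons Expected background photons per pixel.
#' @param read_noise Camera Gaussian read noise SD (photons).
#' @param seed RNG seed.
#' @return List of class `spt_sim_config`.
#' @export
spt_sim_config <- function(D_true = 0.8, alpha = 1, dt = 0.032,
                           n_frames = round(30 / 0.032), n_particles = 200,
                           loc_sd = 20, plane_spacing = 400,
                           plane_misalignments = NULL,
                           plane_efficiencies = NULL,
                           efficiency_jitter = 0.15,
                           tile_px = 128L, pixel_size = 0.16,
                           psf_sigma_xy = 0.15, psf_sigma_z = 350,
                           spot_photons = 200, background_photons = 4,
                           read_noise = 2, seed = NULL) {
  check_scalar(D_true, "D_true", positive = TRUE)
  check_scalar(alpha, "alpha")
  if (alpha <= 0 || alpha > 2)
    nm_stop("'alpha' must lie in (0, 2]", "invalid_config")
  check_scalar(dt, "dt", positive = TRUE)
  check_scalar(n_frames, "n_frames", positive = TRUE)
  if (n_frames < 2) nm_stop("'n_frames' must be >= 2", "invalid_config")
  check_scalar(n_particles, "n_particles", positive = TRUE)
  check_scalar(loc_sd, "loc_sd", nonneg = TRUE)
  check_scalar(plane_spacing, "plane_spacing", positive = TRUE)
  if (!is.null(plane_efficiencies)) {
    if (length(plane_efficiencies) != 9L || any(plane_efficiencies <= 0))
      nm_stop("need exactly nine positive plane efficiencies", "invalid_config")
    rel <- plane_efficiencies / mean(plane_efficiencies)
    if (any(rel < 0.70) || any(rel > 1.30))
      nm_stop("plane efficiencies must lie within [0.70, 1.30] of their mean",
              "invalid_config")
  }
  if (!is.null(plane_misalignments) && length(plane_misalignments) != 9L)
    nm_stop("need exactly nine plane misalignment matrices", "invalid_config")
  structure(list(D_true = D_true, alpha = alpha, dt = dt,
                 n_frames = as.integer(n_frames),
                 n_particles = as.integer(n_particles), loc_sd = loc_sd,
                 plane_spacing = plane_spacing,
                 plane_misalignments = plane_misalignments,
                 plane_efficiencies = plane_efficiencies,
                 efficiency_jitter = efficiency_jitter,
                 tile_px = as.integer(tile_px), pixel_size = pixel_size,
                 psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
                 spot_photons = spot_photons,
                 background_photons = background_photons,
                 read_noise = read_noise, seed = seed),
            class = "spt_sim_config")
}

#' Cholesky factor of the fractional-Gaussian-noise covariance
#'
#' Exact covariance of n fGn increments at unit step variance:
#' rho(h) = 0.5 * (|h+1|^2H - 2|h|^2H + |h-1|^2H).
#' @noRd
.fgn_chol <- function(n, H) {
  h <- 0:(n - 1)
  rho <- 0.5 * (abs(h + 1)^(2 * H) - 2 * abs(h)^(2 * H) + abs(h - 1)^(2 * H))
  chol(stats::toeplitz(rho))
}

#' Simulate fractional-Brownian-motion 3D trajectories
#'
#' Each coordinate axis is an independent fractional Brownian motion with
#' Hurst exponent H = alpha/2, scaled so the ensemble 3D mean squared
#' displacement obeys MSD(tau) = 6 * D * tau^alpha exactly in expectation
#' (2 * D * tau^alpha per axis). Increments are drawn through the exact
#' Cholesky factor of the fractional-Gaussian-noise covariance, so the MSD
#' law holds at every lag, not just asymptotically. Gaussian localization
#' noise of SD `loc_sd` is added to every coordinate.
#'
#' @param cfg An [spt_sim_config()].
#' @param start_xyz Optional n_particles x 3 matrix of starting positions
#'   (um); default all at the origin.
#' @return List of class `trajectory3d` objects; each has `track_id` and a
#'   data.frame `points` with columns `frame`, `x`, `y`, `z` (um) and
#'   `intensity`. The list carries attribute `truth` (D, alpha, dt, loc_sd).
#' @export
simulate_fbm_tracks <- function(cfg, start_xyz = NULL) {
  stopifnot(inherits(cfg, "spt_sim_config"))
  n <- cfg$n_frames
  np <- cfg$n_particles
  H <- cfg$alpha / 2
  step_sd <- sqrt(2 * cfg$D_true * cfg$dt^cfg$alpha)  # per-axis, um
  if (is.null(start_xyz)) start_xyz <- matrix(0, np, 3)
  stopifnot(nrow(start_xyz) == np, ncol(start_xyz) == 3)
  L <- .fgn_chol(n - 1L, H)                            # upper triangular
  tracks <- with_seed(cfg$seed, {
    lapply(seq_len(np), function(p) {
      Z <- matrix(rnorm(3 * (n - 1L)), n - 1L, 3)
      incr <- crossprod(L, Z) * step_sd                # exact fGn increments
      pos <- rbind(start_xyz[p, ], sweep(apply(incr, 2, cumsum), 2,
                                         start_xyz[p, ], `+`))
      if (cfg$loc_sd > 0)
        pos <- pos + matrix(rnorm(3 * n, sd = cfg$loc_sd / 1000), n, 3)
      structure(list(track_id = sprintf("sim_%04d", p),
                     points = data.frame(frame = seq_len(n) - 1L,
                                         x = pos[, 1], y = pos[, 2],
                                         z = pos[, 3], intensity = 1)),
                class = "trajectory3d")
    })
  })
  attr(tracks, "truth") <- list(D = cfg$D_true, alpha = cfg$alpha,
                                dt = cfg$dt, loc_sd = cfg$loc_sd)
  tracks
}

#' Axial depth (um) of each focal plane, plane 1 shallowest
#' @noRd
.plane_depths <- function(spacing_nm) ((1:9) - 5) * spacing_nm / 1000

#' Default identity misalignment list
#' @noRd
.identity_transforms <- function() {
  replicate(9, cbind(diag(2), c(0, 0)), simplify = FALSE)
}

#' Apply a 2x3 affine (rows: x', y') to an n x 2 coordinate matrix
#' @noRd
.affine_apply <- function(m, xy) {
  cbind(m[1, 1] * xy[, 1] + m[1, 2] * xy[, 2] + m[1, 3],
        m[2, 1] * xy[, 1] + m[2, 2] * xy[, 2] + m[2, 3])
}

#' Invert a 2x3 affine transform
#' @noRd
.affine_invert <- function(m) {
  A <- m[, 1:2]
  Ainv <- solve(A)
  cbind(Ainv, -Ainv %*% m[, 3])
}

#' Render trajectories into a nine-plane multifocal movie
#'
#' Each frame is a 3x3 tile (row-major, plane 1 = shallowest = top-left) of
#' sub-images. A particle contributes a 2D Gaussian spot to every tile, with
#' amplitude weighted by a Gaussian axial response centred on that plane's
#' depth (sigma `psf_sigma_z`) and multiplied by the plane's detection
#' efficiency. Tile coordinates are displaced by the plane's ground-truth
#' affine misalignment. Poisson shot noise plus Gaussian read noise is added.
#' Particles outside the lateral field of view or the nine-plane axial span
#' are clipped (with a warning).
#'
#' The lateral origin of the field is at the tile centre: a particle at
#' (0, 0) um appears in the middle of each sub-image.
#'
#' @param tracks List of `trajectory3d` (e.g. from [simulate_fbm_tracks()]).
#' @param cfg An [spt_sim_config()].
#' @param frames Which frame indices (0-based, matching track `frame`) to
#'   render; default all frames in `cfg`.
#' @param noise Logical; add camera noise (default TRUE).
#' @return List of class `mfm_movie`: `frames` (list of (3*tile_px) x
#'   (3*tile_px) matrices), `frame_index`, `calibration` (ground-truth
#'   [plane_calibration()]), `cfg`, and `truth` (efficiencies, transforms).
#' @export
render_mfm_movie <- function(tracks, cfg, frames = NULL, noise = TRUE) {
  stopifnot(inherits(cfg, "spt_sim_config"))
  tile <- cfg$tile_px
  px <- cfg$pixel_size
  depths <- .plane_depths(cfg$plane_spacing)
  half_span <- (max(depths) - min(depths)) / 2 + 2 * cfg$psf_sigma_z / 1000
  eff <- cfg$plane_efficiencies
  mis <- cfg$plane_misalignments
  rendered <- with_seed(cfg$seed, {
    if (is.null(eff)) {
      eff <- if (cfg$efficiency_jitter > 0)
        runif(9, 1 - cfg$efficiency_jitter, 1 + cfg$efficiency_jitter)
      else rep(1, 9)
    }
    if (is.null(mis)) mis <- .identity_transforms()
    if (is.null(frames)) frames <- seq_len(cfg$n_frames) - 1L
    fov_half <- tile * px / 2
    clipped <- FALSE
    sig_px <- cfg$psf_sigma_xy / px
    win <- ceiling(4 * sig_px)
    out <- lapply(frames, function(fr) {
      img <- matrix(cfg$background_photons, 3 * tile, 3 * tile)
      for (tr in tracks) {
        row <- which(tr$points$frame == fr)
        if (length(row) == 0L) next
        p <- tr$points[row[1L], ]
        if (abs(p$x) > fov_half || abs(p$y) > fov_half ||
            abs(p$z) > half_span) { clipped <<- TRUE; next }
        amp_z <- exp(-((p$z - depths)^2) / (2 * (cfg$psf_sigma_z / 1000)^2))
        for (j in 1:9) {
          a <- cfg$spot_photons * amp_z[j] * eff[j]
          if (a < 1e-3) next
          # reference-tile pixel coordinates (pixel centre convention)
          cx <- p$x / px + tile / 2 + 0.5
          cy <- p$y / px + tile / 2 + 0.5
          obs <- .affine_apply(mis[[j]], cbind(cx, cy))
          ox <- obs[1]; oy <- obs[2]
          xs <- max(1, floor(ox - win)):min(tile, ceiling(ox + win))
          ys <- max(1, floor(oy - win)):min(tile, ceiling(oy + win))
          if (length(xs) == 0L || length(ys) == 0L) next
          gx <- exp(-((xs - ox)^2) / (2 * sig_px^2))
          gy <- exp(-((ys - oy)^2) / (2 * sig_px^2))
          spot <- a * outer(gx, gy)
          # tile offset: row-major, plane 1 top-left; x = column, y = row
          tc <- (j - 1) %% 3       # tile column 0..2
          trw <- (j - 1) %/% 3     # tile row 0..2
          img[tc * tile + xs, trw * tile + ys] <-
            img[tc * tile + xs, trw * tile + ys] + spot
        }
      }
      if (noise) {
        img <- matrix(rpois(length(img), img), nrow(img)) +
          rnorm(length(img), sd = cfg$read_noise)
      }
      img
    })
    if (clipped)
      warning("some particles left the field of view or axial span and were clipped")
    list(frames = out, eff = eff, mis = mis, frame_index = frames)
  })
  cal <- plane_calibration(
    transforms = lapply(rendered$mis, .affine_invert),
    spacing = cfg$plane_spacing,
    efficiencies = rendered$eff / mean(rendered$eff))
  structure(list(frames = rendered$frames, frame_index = rendered$frame_index,
                 calibration = cal, cfg = cfg,
                 truth = list(efficiencies = rendered$eff,
                              misalignments = rendered$mis)),
            class = "mfm_movie")
}

#' Render a static fiducial-bead field for plane calibration
#'
#' Beads are placed at shared lateral positions, visible in all nine planes
#' (the axial response is disabled), with the configured per-plane
#' efficiencies and misalignments applied — the standard input for
#' [calibrate_planes()].
#'
#' @param cfg An [spt_sim_config()].
#' @param bead_xy Optional n x 2 matrix of bead positions (um, field-centre
#'   origin); default a 3 x 3 grid of 9 beads spanning the field.
#' @param n_frames Number of frames to render.
#' @return An `mfm_movie` as from [render_mfm_movie()].
#' @export
simulate_bead_field <- function(cfg, bead_xy = NULL, n_frames = 5L) {
  stopifnot(inherits(cfg, "spt_sim_config"))
  if (is.null(bead_xy)) {
    g <- cfg$tile_px * cfg$pixel_size * 0.30 * c(-1, 0, 1)
    bead_xy <- as.matrix(expand.grid(x = g, y = g * 0.8 + 0.37))
  }
  beads <- lapply(seq_len(nrow(bead_xy)), function(i) {
    structure(list(track_id = sprintf("bead_%02d", i),
                   points = data.frame(frame = seq_len(n_frames) - 1L,
                                       x = as.numeric(bead_xy[i, 1]),
                                       y = as.numeric(bead_xy[i, 2]),
                                       z = 0, intensity = 1)),
              class = "trajectory3d")
  })
  cfg_bead <- cfg
  cfg_bead$psf_sigma_z <- 1e9          # visible in every plane
  cfg_bead$n_frames <- as.integer(n_frames)
  render_mfm_movie(beads, cfg_bead, frames = seq_len(n_frames) - 1L)
}
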