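# Multifocal-microscopy 3D single-particle tracking: calibration of the nine
# focal planes (affine alignment, axial spacing, detection efficiencies),
# reassembly of tiled frames into 3D stacks, spot detection, frame-to-frame
# linking, and anomalous-diffusion MSD analysis.

#' Plane calibration for a nine-plane multifocal system
#'
#' @param transforms List of nine 2x3 affine matrices mapping each observed
#'   tile's pixel coordinates to the reference frame.
#' @param spacing Axial separation between adjacent planes (nm).
#' @param efficiencies Nine relative detection-efficiency factors; they are
#'   normalised to mean 1.
#' @return List of class `plane_calibration`.
#' @export
plane_calibration <- function(transforms, spacing = 400, efficiencies = rep(1, 9)) {
  if (length(transforms) != 9L)
    nm_stop("need exactly nine plane transforms", "invalid_config")
  for (m in transforms)
    if (!is.matrix(m) || !all(dim(m) == c(2, 3)))
      nm_stop("each transform must be a 2x3 matrix", "invalid_config")
  check_scalar(spacing, "spacing", positive = TRUE)
  if (length(efficiencies) != 9L || any(efficiencies <= 0))
    nm_stop("need exactly nine positive efficiencies", "invalid_config")
  structure(list(transforms = transforms, spacing = spacing,
                 efficiencies = efficiencies / mean(efficiencies)),
            class = "plane_calibration")
}

#' Write a plane calibration to a YAML file
#' @param cal A [plane_calibration()].
#' @param path Output path.
#' @export
write_plane_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "plane_calibration"))
  yaml::write_yaml(list(
    spacing_nm = cal$spacing,
    efficiencies = as.numeric(cal$efficiencies),
    transforms = lapply(cal$transforms, function(m) as.numeric(t(m)))
  ), path, precision = 15)
}

#' Read a plane calibration written by [write_plane_calibration()]
#' @param path YAML file path.
#' @return A [plane_calibration()].
#' @export
read_plane_calibration <- function(path) {
  y <- yaml::read_yaml(path)
  plane_calibration(
    transforms = lapply(y$transforms, function(v) matrix(v, 2, 3, byrow = TRUE)),
    spacing = y$spacing_nm,
    efficiencies = as.numeric(y$efficiencies))
}

#' Split a tiled multifocal frame into its nine sub-images
#'
#' Row-major tile order, plane 1 (shallowest) top-left. Frames are indexed
#' `[x, y]` with x horizontal.
#' @noRd
.split_tiles <- function(frame) {
  tile <- nrow(frame) %/% 3L
  lapply(1:9, function(j) {
    tc <- (j - 1) %% 3; trw <- (j - 1) %/% 3
    frame[tc * tile + seq_len(tile), trw * tile + seq_len(tile), drop = FALSE]
  })
}

#' Bilinear warp of an image under an affine map
#'
#' `m` maps destination pixel coordinates to source pixel coordinates.
#' Samples outside the source are zero.
#' @noRd
.warp_affine <- function(img, m, out_dim = dim(img)) {
  nx <- out_dim[1]; ny <- out_dim[2]
  grid <- cbind(rep(seq_len(nx), ny), rep(seq_len(ny), each = nx))
  src <- .affine_apply(m, grid)
  sx <- src[, 1]; sy <- src[, 2]
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  val <- numeric(nx * ny)
  get_px <- function(ix, iy) {
    ok <- ix >= 1 & ix <= nrow(img) & iy >= 1 & iy <= ncol(img)
    v <- numeric(length(ix))
    v[ok] <- img[cbind(ix[ok], iy[ok])]
    v
  }
  val <- get_px(x0, y0) * (1 - fx) * (1 - fy) +
    get_px(x0 + 1, y0) * fx * (1 - fy) +
    get_px(x0, y0 + 1) * (1 - fx) * fy +
    get_px(x0 + 1, y0 + 1) * fx * fy
  matrix(val, nx, ny)
}

#' Reassemble one tiled multifocal frame into a calibrated 3D stack
#'
#' Each of the nine sub-images is warped into the reference frame by its
#' affine transform (bilinear interpolation), divided by its detection
#' efficiency, and stacked along z at the calibrated spacing (plane 1
#' shallowest).
#'
#' @param frame A (3*tile) x (3*tile) tiled image matrix.
#' @param cal A [plane_calibration()].
#' @param pixel_size Lateral pixel size (um/px).
#' @return List of class `mfm_stack`: `data` (tile x tile x 9 array),
#'   `pixel_size` (um/px), `spacing` (nm), `depths` (um, per plane).
#' @export
reassemble_stack <- function(frame, cal, pixel_size = 0.16) {
  if (is.null(cal) || !inherits(cal, "plane_calibration"))
    nm_stop("a plane_calibration is required", "missing_calibration")
  if (nrow(frame) %% 3L != 0L || ncol(frame) %% 3L != 0L)
    nm_stop("frame dimensions must divide into 3x3 tiles", "invalid_input")
  tiles <- .split_tiles(frame)
  tile <- nrow(tiles[[1]])
  arr <- array(0, dim = c(tile, tile, 9))
  for (j in 1:9) {
    m <- cal$transforms[[j]]
    ident <- isTRUE(all.equal(m, cbind(diag(2), c(0, 0)), tolerance = 1e-12))
    aligned <- if (ident) tiles[[j]] else .warp_affine(tiles[[j]], .affine_invert(m))
    arr[, , j] <- aligned / cal$efficiencies[j]
  }
  structure(list(data = arr, pixel_size = pixel_size, spacing = cal$spacing,
                 depths = .plane_depths(cal$spacing)),
            class = "mfm_stack")
}

#' Preprocess a reassembled stack
#'
#' Deterministic, order-fixed: (1) per-plane percentile background
#' subtraction, (2) optional Richardson-Lucy deconvolution with a Gaussian
#' PSF (3-5 iterations), (3) optional Gaussian denoising. Negative values
#' after background subtraction are clamped to zero.
#'
#' @param stack An `mfm_stack`.
#' @param background Subtract the per-plane background (logical). Negative
#'   residuals are kept so that downstream robust noise estimates stay
#'   meaningful.
#' @param bg_quantile Quantile used as the background estimate (default
#'   median).
#' @param rl_iterations Richardson-Lucy iterations (0 = off; allowed 3-5).
#' @param rl_sigma_px PSF sigma for deconvolution (pixels).
#' @param denoise_sigma_px Gaussian denoising sigma (0 = off; pixels).
#' @return The preprocessed `mfm_stack`.
#' @export
preprocess_stack <- function(stack, background = TRUE, bg_quantile = 0.5,
                             rl_iterations = 0L, rl_sigma_px = 1.0,
                             denoise_sigma_px = 0) {
  stopifnot(inherits(stack, "mfm_stack"))
  if (rl_iterations != 0L && (rl_iterations < 3L || rl_iterations > 5L))
    nm_stop("rl_iterations must be 0 (off) or within 3-5", "invalid_config")
  arr <- stack$data
  if (background) {
    for (j in seq_len(dim(arr)[3])) {
      b <- stats::quantile(arr[, , j], bg_quantile, names = FALSE)
      arr[, , j] <- arr[, , j] - b
    }
  }
  if (rl_iterations > 0L) {
    psf <- .gauss_kernel(rl_sigma_px)
    for (j in seq_len(dim(arr)[3]))
      arr[, , j] <- .richardson_lucy(arr[, , j], psf, rl_iterations)
  }
  if (denoise_sigma_px > 0) {
    for (j in seq_len(dim(arr)[3]))
      arr[, , j] <- .conv2_kernel(arr[, , j], .gauss_kernel(denoise_sigma_px))
  }
  stack$data <- arr
  stack
}

#' Normalised 2D Gaussian kernel
#' @noRd
.gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- -r:r
  k <- exp(-outer(x^2, x^2, `+`) / (2 * sigma^2))
  k / sum(k)
}

#' 2D convolution with reflected borders via EBImage
#' @noRd
.conv2_kernel <- function(img, kern) {
  as.matrix(EBImage::filter2(EBImage::Image(img), kern, boundary = "replicate"))
}

#' Richardson-Lucy deconvolution (symmetric PSF)
#' @noRd
.richardson_lucy <- function(img, psf, iterations) {
  est <- pmax(img, .Machine$double.eps)
  obs <- pmax(img, 0)
  for (i in seq_len(iterations)) {
    blur <- .conv2_kernel(est, psf)
    ratio <- obs / pmax(blur, .Machine$double.eps)
    est <- est * .conv2_kernel(ratio, psf)
  }
  est
}

#' Sub-sample quadratic-interpolated peak offset from three log-intensities
#'
#' Exact for a Gaussian profile sampled at three equidistant points.
#' @noRd
.log_parabola_offset <- function(Im1, I0, Ip1) {
  v <- log(pmax(c(Im1, I0, Ip1), .Machine$double.eps))
  den <- v[1] - 2 * v[2] + v[3]
  if (!is.finite(den) || den >= 0) return(0)
  off <- 0.5 * (v[1] - v[3]) / den
  max(-1, min(1, off))
}

#' Detect particles in a reassembled 3D stack
#'
#' Local maxima (in the 3x3x3 neighbourhood) above a robust threshold
#' (median + `c_mad` * MAD of the stack) are refined to sub-pixel and
#' sub-plane coordinates by log-quadratic interpolation along x, y and z —
#' exact for Gaussian lateral spots and a Gaussian axial response. Positions
#' are returned in um with the lateral origin at the field centre.
#'
#' @param stack An `mfm_stack` (preprocessed).
#' @param c_mad Threshold multiplier on the MAD above the median.
#' @param min_sep_px Minimum lateral separation between detections (pixels);
#'   of two maxima closer than this, the brighter wins.
#' @return data.frame with columns `x`, `y`, `z` (um), `plane`, `intensity`.
#' @export
detect_particles <- function(stack, c_mad = 8, min_sep_px = 4) {
  stopifnot(inherits(stack, "mfm_stack"))
  arr <- stack$data
  nx <- dim(arr)[1]; ny <- dim(arr)[2]; nz <- dim(arr)[3]
  scale <- stats::mad(arr)
  if (scale == 0) scale <- stats::sd(arr)
  thr <- stats::median(arr) + c_mad * scale
  cand <- which(arr > thr, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      plane = integer(), intensity = numeric()))
  is_max <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ix <- cand[i, 1]; iy <- cand[i, 2]; iz <- cand[i, 3]
    nb <- arr[max(1, ix - 1):min(nx, ix + 1),
              max(1, iy - 1):min(ny, iy + 1),
              max(1, iz - 1):min(nz, iz + 1)]
    is_max[i] <- arr[ix, iy, iz] >= max(nb)
  }
  cand <- cand[is_max, , drop = FALSE]
  if (nrow(cand) == 0L)
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      plane = integer(), intensity = numeric()))
  # suppress duplicate maxima closer than min_sep_px laterally
  inten <- arr[cand]
  ord <- order(inten, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]; inten <- inten[ord]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      later <- (i + 1):nrow(cand)
      d2 <- (cand[later, 1] - cand[i, 1])^2 + (cand[later, 2] - cand[i, 2])^2
      keep[later][d2 < min_sep_px^2] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]; inten <- inten[keep]
  px <- stack$pixel_size
  res <- lapply(seq_len(nrow(cand)), function(i) {
    ix <- cand[i, 1]; iy <- cand[i, 2]; iz <- cand[i, 3]
    dx <- if (ix > 1 && ix < nx)
      .log_parabola_offset(arr[ix - 1, iy, iz], arr[ix, iy, iz], arr[ix + 1, iy, iz])
    else 0
    dy <- if (iy > 1 && iy < ny)
      .log_parabola_offset(arr[ix, iy - 1, iz], arr[ix, iy, iz], arr[ix, iy + 1, iz])
    else 0
    dz <- if (iz > 1 && iz < nz)
      .log_parabola_offset(arr[ix, iy, iz - 1], arr[ix, iy, iz], arr[ix, iy, iz + 1])
    else 0
    data.frame(
      x = (ix + dx - nx / 2 - 0.5) * px,
      y = (iy + dy - ny / 2 - 0.5) * px,
      z = stack$depths[iz] + dz * stack$spacing / 1000,
      plane = iz, intensity = inten[i])
  })
  do.call(rbind, res)
}

#' Enumerate all matchings of a small bipartite component, keeping the one
#' with the most links and, among those, minimal total squared displacement.
#' @noRd
.best_matching <- function(cost) {
  na <- nrow(cost); nb <- ncol(cost)
  best <- list(links = -1L, total = Inf, assign = rep(NA_integer_, na))
  recurse <- function(i, used_b, assign, links, total) {
    if (i > na) {
      if (links > best$links ||
          (links == best$links && total < best$total)) {
        best <<- list(links = links, total = total, assign = assign)
      }
      return(invisible())
    }
    # option: leave detection i unmatched
    recurse(i + 1L, used_b, assign, links, total)
    for (j in seq_len(nb)) {
      if (!used_b[j] && is.finite(cost[i, j])) {
        used_b[j] <- TRUE; assign[i] <- j
        recurse(i + 1L, used_b, assign, links + 1L, total + cost[i, j])
        used_b[j] <- FALSE; assign[i] <- NA_integer_
      }
    }
  }
  recurse(1L, rep(FALSE, nb), rep(NA_integer_, na), 0L, 0)
  best$assign
}

#' Link localizations into 3D trajectories
#'
#' Frame-to-frame assignment: candidate links are detection pairs within
#' `max_disp`; within each connected conflict component the assignment
#' maximising the number of links and minimising total squared displacement
#' is found exactly when the component is small (exhaustive enumeration),
#' with greedy nearest-neighbour used for larger components. No gap closing:
#' a missed frame terminates the track. Tracks shorter than `min_len` frames
#' are discarded.
#'
#' @param locs data.frame with columns `frame`, `x`, `y`, `z` (um) and
#'   optionally `intensity`, sorted by frame.
#' @param max_disp Maximum frame-to-frame displacement (nm).
#' @param min_len Minimum track length (frames).
#' @param max_exhaustive Components with at most this many nodes are solved
#'   exactly.
#' @return List of `trajectory3d`.
#' @export
link_tracks <- function(locs, max_disp = 400, min_len = 10L,
                        max_exhaustive = 8L) {
  needed <- c("frame", "x", "y", "z")
  if (!all(needed %in% names(locs)))
    nm_stop("locs needs columns frame, x, y, z", "invalid_input")
  if (nrow(locs) == 0L) return(list())
  if (is.null(locs$intensity)) locs$intensity <- 1
  locs <- locs[order(locs$frame), , drop = FALSE]
  max_d_um <- max_disp / 1000
  frames <- sort(unique(locs$frame))
  # active track state: list of data.frames under construction
  open_tracks <- list()
  open_pos <- matrix(numeric(0), 0, 3)
  done_tracks <- list()
  for (fr in frames) {
    det <- locs[locs$frame == fr, , drop = FALSE]
    npr <- nrow(open_pos); nde <- nrow(det)
    assign_to <- rep(NA_integer_, nde)
    if (npr > 0L && nde > 0L) {
      d2 <- outer(det$x, open_pos[, 1], `-`)^2 +
        outer(det$y, open_pos[, 2], `-`)^2 +
        outer(det$z, open_pos[, 3], `-`)^2
      cost <- d2
      cost[sqrt(d2) > max_d_um] <- Inf
      # also break links across non-consecutive frames (no gap closing)
      prev_frames <- vapply(open_tracks, function(t) t$frame[nrow(t)], numeric(1))
      cost[, prev_frames != fr - 1L] <- Inf
      # connected components of the candidate graph
      if (any(is.finite(cost))) {
        comp_d <- rep(0L, nde); comp_t <- rep(0L, npr); ncomp <- 0L
        for (i in seq_len(nde)) {
          if (comp_d[i] != 0L || !any(is.finite(cost[i, ]))) next
          ncomp <- ncomp + 1L
          queue_d <- i
          while (length(queue_d) > 0L) {
            di <- queue_d[1]; queue_d <- queue_d[-1]
            if (comp_d[di] != 0L) next
            comp_d[di] <- ncomp
            tj <- which(is.finite(cost[di, ]) & comp_t == 0L)
            for (t1 in tj) {
              comp_t[t1] <- ncomp
              queue_d <- c(queue_d, which(is.finite(cost[, t1]) & comp_d == 0L))
            }
          }
        }
        for (cc in seq_len(ncomp)) {
          di <- which(comp_d == cc); tj <- which(comp_t == cc)
          sub <- cost[di, tj, drop = FALSE]
          if (length(di) + length(tj) <= max_exhaustive) {
            a <- .best_matching(sub)
            assign_to[di] <- tj[a]
          } else {
            # greedy by increasing cost
            edges <- which(is.finite(sub), arr.ind = TRUE)
            edges <- edges[order(sub[edges]), , drop = FALSE]
            used_d <- logical(length(di)); used_t <- logical(length(tj))
            for (e in seq_len(nrow(edges))) {
              r <- edges[e, 1]; cl <- edges[e, 2]
              if (!used_d[r] && !used_t[cl]) {
                used_d[r] <- TRUE; used_t[cl] <- TRUE
                assign_to[di[r]] <- tj[cl]
              }
            }
          }
        }
      }
    }
    # close tracks that received no detection
    extended <- rep(FALSE, npr)
    new_open <- list(); new_pos <- NULL
    for (i in seq_len(nde)) {
      j <- assign_to[i]
      row <- det[i, c("frame", "x", "y", "z", "intensity")]
      if (!is.na(j)) {
        extended[j] <- TRUE
        new_open[[length(new_open) + 1L]] <- rbind(open_tracks[[j]], row)
      } else {
        new_open[[length(new_open) + 1L]] <- row
      }
      new_pos <- rbind(new_pos, c(row$x, row$y, row$z))
    }
    for (j in which(!extended)) done_tracks[[length(done_tracks) + 1L]] <- open_tracks[[j]]
    open_tracks <- new_open
    open_pos <- if (is.null(new_pos)) matrix(numeric(0), 0, 3) else new_pos
  }
  done_tracks <- c(done_tracks, open_tracks)
  done_tracks <- Filter(function(t) nrow(t) >= min_len, done_tracks)
  lapply(seq_along(done_tracks), function(i) {
    pts <- done_tracks[[i]]
    rownames(pts) <- NULL
    structure(list(track_id = sprintf("track_%04d", i), points = pts),
              class = "trajectory3d")
  })
}

#' Time-averaged 3D mean squared displacement of one trajectory
#'
#' msd(tau = n * dt) = mean over i of |r(i + n) - r(i)|^2 for
#' n = 1 .. floor(max_lag_fraction * N). Frames must be consecutive.
#'
#' @param track A `trajectory3d` with >= 10 points.
#' @param dt Frame interval (s).
#' @param max_lag_fraction Largest lag as a fraction of track length.
#' @return List with `lags` (s) and `msd` (um^2), plus `n_points`.
#' @export
compute_msd <- function(track, dt = 0.032, max_lag_fraction = 0.25) {
  stopifnot(inherits(track, "trajectory3d"))
  pts <- track$points
  N <- nrow(pts)
  if (N < 10L) nm_stop("track shorter than 10 points", "track_too_short")
  max_lag <- max(1L, floor(max_lag_fraction * N))
  r <- as.matrix(pts[, c("x", "y", "z")])
  msd <- vapply(seq_len(max_lag), function(n) {
    d <- r[(n + 1):N, , drop = FALSE] - r[1:(N - n), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
  list(lags = seq_len(max_lag) * dt, msd = msd, n_points = N)
}

#' Fit the anomalous-diffusion model to an MSD curve
#'
#' Weighted least squares of msd(tau) = 6 * D * tau^alpha + 6 * sigma_loc^2
#' over the first `n_fit` lags. Weights are inverse-variance with the
#' variance of a time-averaged MSD approximated by the standard
#' (Qian) formula var(msd_n) ~ msd_n^2 * (2n^2 + 1) / (3n (N - n + 1)).
#' The localization-noise offset is co-fitted with a floor at zero by
#' default, or fixed when `loc_sd` is supplied.
#'
#' @param lags Lag times (s), strictly increasing, >= 4 values.
#' @param msd MSD values (um^2).
#' @param loc_sd If non-NULL, localization SD (nm) fixing the offset at
#'   6 * (loc_sd/1000)^2.
#' @param n_points Track length used for the weight formula (NULL = equal
#'   weights).
#' @param n_fit Number of leading lags used in the fit (default 10).
#' @return List of class `msd_fit`: `lags`, `msd`, `D` (um^2/s^alpha),
#'   `alpha`, `offset` (um^2), `se_D`, `se_alpha`, `D_app` (um^2/s, apparent
#'   coefficient msd(tau_1)/(6 tau_1)), `converged`.
#' @export
fit_anomalous <- function(lags, msd, loc_sd = NULL, n_points = NULL,
                          n_fit = 10L) {
  if (length(lags) != length(msd) || length(lags) < 4L)
    nm_stop("need at least 4 (lag, msd) points", "invalid_input")
  if (any(diff(lags) <= 0))
    nm_stop("lags must be strictly increasing", "invalid_input")
  k <- min(n_fit, length(lags))
  tau <- lags[1:k]; y <- msd[1:k]
  w <- if (!is.null(n_points)) {
    n <- seq_len(k)
    v <- pmax(y, .Machine$double.eps)^2 * (2 * n^2 + 1) / (3 * n * (n_points - n + 1))
    1 / pmax(v, .Machine$double.eps)
  } else rep(1, k)
  offset_fixed <- if (!is.null(loc_sd)) 6 * (loc_sd / 1000)^2 else NULL
  fail <- function() list(lags = lags, msd = msd, D = NA_real_,
                          alpha = NA_real_, offset = NA_real_,
                          se_D = NA_real_, se_alpha = NA_real_,
                          D_app = msd[1] / (6 * lags[1]), converged = FALSE)
  if (all(y <= 0)) return(structure(fail(), class = "msd_fit"))
  # log-log start values on offset-corrected positive part
  y0 <- y - if (is.null(offset_fixed)) 0 else offset_fixed
  pos <- y0 > 0
  if (sum(pos) >= 2L) {
    cf <- unname(stats::coef(stats::lm(log(y0[pos]) ~ log(tau[pos]))))
    a_start <- min(max(cf[2], 0.1), 2)
    D_start <- exp(cf[1]) / 6
  } else {
    a_start <- 1; D_start <- max(y[1] / (6 * tau[1]), 1e-6)
  }
  dat <- data.frame(tau = tau, y = y)
  fit <- NULL
  # a start sitting numerically on the optimum can trip the LM gradient
  # check, so retry from mildly perturbed starts
  for (fac in c(1, 1.1, 0.8)) {
    fit <- tryCatch({
      if (is.null(offset_fixed)) {
        minpack.lm::nlsLM(y ~ 6 * D * tau^alpha + 6 * s2, data = dat,
                          start = list(D = fac * D_start,
                                       alpha = min(fac * a_start, 2), s2 = 0),
                          lower = c(1e-12, 0.01, 0), upper = c(Inf, 2, Inf),
                          weights = w,
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(y ~ 6 * D * tau^alpha + offset_fixed, data = dat,
                          start = list(D = fac * D_start,
                                       alpha = min(fac * a_start, 2)),
                          lower = c(1e-12, 0.01), upper = c(Inf, 2),
                          weights = w,
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(structure(fail(), class = "msd_fit"))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    rep(NA_real_, length(cf)))
  offset <- if (is.null(offset_fixed)) 6 * cf[["s2"]] else offset_fixed
  structure(list(lags = lags, msd = msd, D = cf[["D"]], alpha = cf[["alpha"]],
                 offset = offset,
                 se_D = unname(se[1]), se_alpha = unname(se[2]),
                 D_app = msd[1] / (6 * lags[1]),
                 converged = is.finite(cf[["D"]]) && cf[["D"]] > 0),
            class = "msd_fit")
}

#' Compute MSDs and anomalous-diffusion fits for a list of tracks
#'
#' Convenience wrapper over [compute_msd()] and [fit_anomalous()]: tracks
#' whose MSD has fewer than 4 usable lags (or that fail to fit) yield a
#' flagged non-converged `msd_fit` instead of an error.
#'
#' @param tracks List of `trajectory3d`.
#' @param dt Frame interval (s).
#' @param max_lag_fraction Passed to [compute_msd()].
#' @param ... Passed to [fit_anomalous()].
#' @return List of `msd_fit` objects (one per track).
#' @export
fit_tracks_msd <- function(tracks, dt = 0.032, max_lag_fraction = 0.25, ...) {
  lapply(tracks, function(tr) {
    tryCatch({
      m <- compute_msd(tr, dt = dt, max_lag_fraction = max_lag_fraction)
      f <- fit_anomalous(m$lags, m$msd, n_points = m$n_points, ...)
      f$track_id <- tr$track_id
      f
    }, nucmech_error = function(e) {
      structure(list(lags = numeric(), msd = numeric(), D = NA_real_,
                     alpha = NA_real_, offset = NA_real_, se_D = NA_real_,
                     se_alpha = NA_real_, D_app = NA_real_, converged = FALSE,
                     track_id = tr$track_id, error = conditionMessage(e)),
                class = "msd_fit")
    })
  })
}

#' Pool per-track diffusion fits into a per-condition summary
#'
#' @param fits List of `msd_fit` objects.
#' @param condition Condition label.
#' @return One-row data.frame: `condition`, `n_tracks`, `D_mean`, `D_sem`,
#'   `alpha_mean`, `alpha_sem`, `D_app_mean`, `sem_defined`.
#' @export
summarize_diffusion <- function(fits, condition = "condition") {
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(conv) == 0L)
    nm_stop("no converged MSD fits", "empty_input")
  D <- vapply(conv, function(f) f$D, numeric(1))
  alpha <- vapply(conv, function(f) f$alpha, numeric(1))
  D_app <- vapply(conv, function(f) f$D_app, numeric(1))
  data.frame(condition = as.character(condition), n_tracks = length(conv),
             D_mean = mean(D), D_sem = sem(D),
             alpha_mean = mean(alpha), alpha_sem = sem(alpha),
             D_app_mean = mean(D_app), sem_defined = length(conv) >= 2L,
             stringsAsFactors = FALSE)
}

#' Estimate a plane calibration from a fiducial bead movie
#'
#' Frames are averaged, spots are detected per tile (local maxima refined by
#' log-quadratic interpolation), matched to the reference plane (plane 5,
#' the central one) by nearest neighbour, and each plane's affine transform
#' is estimated by least squares. Efficiencies are per-plane mean fiducial
#' intensities normalised to the overall mean. The axial spacing is taken
#' from `spacing` (nominal 400 nm): fiducials at a shared depth carry no
#' spacing information.
#'
#' @param movie An `mfm_movie` (e.g. from [simulate_bead_field()]) or a list
#'   of tiled frame matrices.
#' @param spacing Axial plane spacing to record (nm).
#' @param c_mad Detection threshold multiplier (median + c_mad * MAD per
#'   tile).
#' @param match_radius_px Maximum distance (px) for matching a fiducial to
#'   its reference-plane position.
#' @return A [plane_calibration()].
#' @export
calibrate_planes <- function(movie, spacing = 400, c_mad = 8,
                             match_radius_px = 10) {
  frames <- if (inherits(movie, "mfm_movie")) movie$frames else movie
  avg <- Reduce(`+`, frames) / length(frames)
  tiles <- .split_tiles(avg)
  tile <- nrow(tiles[[1]])
  spots <- lapply(tiles, .detect_spots_2d, c_mad = c_mad)
  ref <- spots[[5]]
  if (is.null(ref) || nrow(ref) < 4L)
    nm_stop("fewer than 4 fiducials detected in the reference plane",
            "calibration_error")
  transforms <- vector("list", 9)
  mean_int <- numeric(9)
  for (j in 1:9) {
    sp <- spots[[j]]
    if (is.null(sp) || nrow(sp) < 4L)
      nm_stop(sprintf("fewer than 4 fiducials detected in plane %d", j),
              "calibration_error")
    # match each observed spot to the nearest reference spot
    d2 <- outer(sp$x, ref$x, `-`)^2 + outer(sp$y, ref$y, `-`)^2
    nearest <- apply(d2, 1, which.min)
    dist <- sqrt(d2[cbind(seq_len(nrow(sp)), nearest)])
    ok <- dist <= match_radius_px & !duplicated(nearest)
    if (sum(ok) < 4L)
      nm_stop(sprintf("fewer than 4 matched fiducials in plane %d", j),
              "calibration_error")
    obs <- sp[ok, ]; tgt <- ref[nearest[ok], ]
    fx <- stats::lm(tgt$x ~ obs$x + obs$y)
    fy <- stats::lm(tgt$y ~ obs$x + obs$y)
    transforms[[j]] <- rbind(c(stats::coef(fx)[2], stats::coef(fx)[3], stats::coef(fx)[1]),
                             c(stats::coef(fy)[2], stats::coef(fy)[3], stats::coef(fy)[1]))
    mean_int[j] <- mean(sp$intensity[ok])
  }
  plane_calibration(transforms = transforms, spacing = spacing,
                    efficiencies = mean_int / mean(mean_int))
}

#' Detect 2D spots in one tile (local maxima + sub-pixel refinement)
#' @noRd
.detect_spots_2d <- function(img, c_mad = 8, min_sep_px = 4) {
  thr <- stats::median(img) + c_mad * stats::mad(img)
  nx <- nrow(img); ny <- ncol(img)
  cand <- which(img > thr, arr.ind = TRUE)
  cand <- cand[cand[, 1] > 1 & cand[, 1] < nx &
                 cand[, 2] > 1 & cand[, 2] < ny, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  is_max <- vapply(seq_len(nrow(cand)), function(i) {
    ix <- cand[i, 1]; iy <- cand[i, 2]
    img[ix, iy] >= max(img[(ix - 1):(ix + 1), (iy - 1):(iy + 1)])
  }, logical(1))
  cand <- cand[is_max, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  inten <- img[cand]
  ord <- order(inten, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]; inten <- inten[ord]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i] || i == nrow(cand)) next
    later <- (i + 1):nrow(cand)
    d2 <- (cand[later, 1] - cand[i, 1])^2 + (cand[later, 2] - cand[i, 2])^2
    keep[later][d2 < min_sep_px^2] <- FALSE
  }
  cand <- cand[keep, , drop = FALSE]; inten <- inten[keep]
  res <- lapply(seq_len(nrow(cand)), function(i) {
    ix <- cand[i, 1]; iy <- cand[i, 2]
    # local background-corrected window intensity
    r <- 3L
    xs <- max(1, ix - r):min(nx, ix + r)
    ys <- max(1, iy - r):min(ny, iy + r)
    wint <- sum(img[xs, ys] - stats::median(img))
    data.frame(
      x = ix + .log_parabola_offset(img[ix - 1, iy], img[ix, iy], img[ix + 1, iy]),
      y = iy + .log_parabola_offset(img[ix, iy - 1], img[ix, iy], img[ix, iy + 1]),
      intensity = wint)
  })
  do.call(rbind, res)
}

#' Track a multifocal movie end to end
#'
#' For every frame: reassemble the nine tiles with the calibration,
#' preprocess, detect particles; finally link detections into trajectories.
#'
#' @param movie An `mfm_movie` or list of tiled frame matrices.
#' @param cal A [plane_calibration()].
#' @param pixel_size Lateral pixel size (um/px).
#' @param max_disp,min_len Linking parameters (nm, frames).
#' @param c_mad Detection threshold multiplier.
#' @param preprocess_args List of arguments passed to [preprocess_stack()].
#' @return List with `tracks` (list of `trajectory3d`) and `localizations`
#'   (data.frame).
#' @export
track_movie <- function(movie, cal, pixel_size = NULL, max_disp = 400,
                        min_len = 10L, c_mad = 8,
                        preprocess_args = list(background = TRUE)) {
  frames <- if (inherits(movie, "mfm_movie")) movie$frames else movie
  fidx <- if (inherits(movie, "mfm_movie")) movie$frame_index
  else seq_along(frames) - 1L
  if (is.null(pixel_size)) {
    pixel_size <- if (inherits(movie, "mfm_movie")) movie$cfg$pixel_size else 0.16
  }
  locs <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    st <- reassemble_stack(frames[[i]], cal, pixel_size)
    st <- do.call(preprocess_stack, c(list(st), preprocess_args))
    det <- detect_particles(st, c_mad = c_mad)
    if (nrow(det) > 0L) det$frame <- fidx[i]
    locs[[i]] <- det
  }
  locs <- do.call(rbind, locs[!vapply(locs, is.null, logical(1))])
  if (is.null(locs) || nrow(locs) == 0L)
    return(list(tracks = list(), localizations = data.frame()))
  tracks <- link_tracks(locs[, c("frame", "x", "y", "z", "intensity")],
                        max_disp = max_disp, min_len = min_len)
  list(tracks = tracks, localizations = locs)
}
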