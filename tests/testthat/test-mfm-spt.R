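test_that("plane calibration recovers shifts, scale and efficiencies", {
  set.seed(31)
  mis <- lapply(1:9, function(j) {
    if (j == 5) cbind(diag(2), c(0, 0))
    else if (j == 6) cbind(diag(2), c(3.2, -1.7))   # known shift on plane 6
    else cbind(matrix(c(1, 0, 0, 1) + rnorm(4, 0, 0.002), 2, 2),
               runif(2, -4, 4))
  })
  eff <- runif(9, 0.85, 1.15)
  cfg <- spt_sim_config(n_particles = 1, seed = 7,
                        plane_misalignments = mis, plane_efficiencies = eff)
  beads <- simulate_bead_field(cfg, n_frames = 10)
  cal <- calibrate_planes(beads)

  pts <- rbind(c(30, 30), c(100, 40), c(64, 100))
  for (j in 1:9) {
    tru <- nucmech:::.affine_invert(mis[[j]])
    err <- max(abs(nucmech:::.affine_apply(tru, pts) -
                     nucmech:::.affine_apply(cal$transforms[[j]], pts)))
    expect_lt(err, 0.1)
  }
  # identity plane estimated within 0.05 px
  err5 <- max(abs(pts - nucmech:::.affine_apply(cal$transforms[[5]], pts)))
  expect_lt(err5, 0.05)
  # efficiencies within 2% of truth
  expect_lt(max(abs(cal$efficiencies / (eff / mean(eff)) - 1)), 0.02)
})

test_that("calibration fails with too few fiducials", {
  cfg <- spt_sim_config(n_particles = 1, seed = 7)
  beads <- simulate_bead_field(cfg, bead_xy = cbind(c(-3, 3), c(-3, 3)),
                               n_frames = 3)
  expect_error(calibrate_planes(beads), class = "calibration_error")
})

test_that("reassembly divides by plane efficiency and validates input", {
  tile <- 30
  fr <- matrix(5, 3 * tile, 3 * tile)
  eff <- rep(1, 9); eff[4] <- 2
  cal <- plane_calibration(replicate(9, cbind(diag(2), c(0, 0)),
                                     simplify = FALSE), 400, eff)
  # calibration normalises efficiencies to mean 1; undo for the check
  st <- reassemble_stack(fr, cal, 0.16)
  expect_equal(st$data[, , 4] * cal$efficiencies[4], matrix(5, tile, tile))
  expect_equal(st$data[1, 1, 4] / st$data[1, 1, 1],
               cal$efficiencies[1] / cal$efficiencies[4])

  expect_error(reassemble_stack(matrix(0, 31, 31), cal), class = "invalid_input")
  expect_error(reassemble_stack(fr, NULL), class = "missing_calibration")
})

test_that("preprocessing removes constant background and RL sharpens a blurred point", {
  tile <- 33
  cal <- plane_calibration(replicate(9, cbind(diag(2), c(0, 0)),
                                     simplify = FALSE), 400)
  # all-zeros stack stays zero
  st0 <- reassemble_stack(matrix(0, 3 * tile, 3 * tile), cal)
  expect_true(all(preprocess_stack(st0)$data == 0))

  # constant background b is removed (to within 2%)
  stb <- reassemble_stack(matrix(7.3, 3 * tile, 3 * tile), cal)
  expect_lt(max(abs(preprocess_stack(stb)$data)), 0.02 * 7.3)

  # RL iterations strictly increase the peak-to-total ratio of a blurred point
  point <- matrix(0, tile, tile); point[17, 17] <- 100
  blurred <- nucmech:::.conv2_kernel(point, nucmech:::.gauss_kernel(1.5))
  deconv <- nucmech:::.richardson_lucy(blurred, nucmech:::.gauss_kernel(1.5), 3)
  expect_gt(max(deconv) / sum(deconv), max(blurred) / sum(blurred))
  expect_error(preprocess_stack(st0, rl_iterations = 2),
               class = "invalid_config")
})

test_that("detection localises noiseless spots to (20, 20, 100) nm and handles edge cases", {
  cfg <- spt_sim_config(n_particles = 2, n_frames = 2, seed = 1,
                        plane_efficiencies = rep(1, 9))
  pos <- data.frame(x = c(-1.03, 1.57), y = c(0.41, -2.11), z = c(-0.13, 0.37))
  tracks <- lapply(1:2, function(i) structure(list(
    track_id = paste0("t", i),
    points = data.frame(frame = 0, x = pos$x[i], y = pos$y[i], z = pos$z[i],
                        intensity = 1)), class = "trajectory3d"))
  mv <- render_mfm_movie(tracks, cfg, frames = 0, noise = FALSE)
  st <- preprocess_stack(reassemble_stack(mv$frames[[1]], mv$calibration,
                                          cfg$pixel_size))
  det <- detect_particles(st)
  expect_equal(nrow(det), 2)     # two spots 2+ um apart -> two detections
  det <- det[order(det$x), ]
  for (i in 1:2) {
    expect_lt(abs(det$x[i] - pos$x[i]), 0.020)
    expect_lt(abs(det$y[i] - pos$y[i]), 0.020)
    expect_lt(abs(det$z[i] - pos$z[i]), 0.100)
  }

  # empty stack -> empty result
  cal <- plane_calibration(replicate(9, cbind(diag(2), c(0, 0)),
                                     simplify = FALSE), 400)
  st0 <- reassemble_stack(matrix(0, 96, 96), cal)
  expect_equal(nrow(detect_particles(st0)), 0)
})

test_that("linker reproduces simple cases and respects max_disp / min_len", {
  # one particle drifting slowly for 20 frames -> one track of length 20
  locs <- data.frame(frame = 0:19, x = 0.01 * (0:19), y = 0, z = 0,
                     intensity = 1)
  tr <- link_tracks(locs, max_disp = 400, min_len = 10)
  expect_length(tr, 1)
  expect_equal(nrow(tr[[1]]$points), 20)

  # a 9-frame track is discarded at min_len = 10
  tr9 <- link_tracks(locs[1:9, ], max_disp = 400, min_len = 10)
  expect_length(tr9, 0)
  expect_length(link_tracks(locs[1:9, ], max_disp = 400, min_len = 9), 1)

  # a displacement beyond max_disp splits the track into two 10-frame halves
  locs2 <- locs
  locs2$x[11:20] <- locs2$x[11:20] + 5
  tr2 <- link_tracks(locs2, max_disp = 400, min_len = 10)
  expect_length(tr2, 2)
  expect_equal(vapply(tr2, function(t) nrow(t$points), integer(1)), c(10L, 10L))
  # with a stricter minimum both fragments are discarded
  expect_length(link_tracks(locs2, max_disp = 400, min_len = 11), 0)

  # two far-apart particles -> two tracks matching the ground-truth partition
  locs3 <- rbind(transform(locs, x = x, y = 0),
                 transform(locs, x = x + 3, y = 3))
  locs3 <- locs3[order(locs3$frame), ]
  tr3 <- link_tracks(locs3, max_disp = 400, min_len = 10)
  expect_length(tr3, 2)
  ys <- sort(vapply(tr3, function(t) t$points$y[1], numeric(1)))
  expect_equal(ys, c(0, 3))
})

test_that("linker equals brute-force optimal assignment on <= 3 particles", {
  set.seed(99)
  for (rep in 1:5) {
    # three Brownian walkers with moderate separation so conflicts happen
    nfr <- 12
    base <- matrix(runif(6, -0.3, 0.3), 3, 2)
    locs <- do.call(rbind, lapply(0:(nfr - 1), function(f) {
      data.frame(frame = f,
                 x = base[, 1] + rnorm(3, 0, 0.08),
                 y = base[, 2] + rnorm(3, 0, 0.08),
                 z = rnorm(3, 0, 0.08), intensity = 1)
    }))
    got <- link_tracks(locs, max_disp = 400, min_len = 2)
    want <- oracle_link_bruteforce(locs, 400, 2)
    # same multiset of track lengths and same total linked path cost
    cost_of <- function(pts) sum(diff(pts$x)^2 + diff(pts$y)^2 + diff(pts$z)^2)
    expect_equal(sort(vapply(got, function(t) nrow(t$points), integer(1))),
                 sort(vapply(want, nrow, integer(1))))
    expect_equal(sum(vapply(got, function(t) cost_of(t$points), numeric(1))),
                 sum(vapply(want, cost_of, numeric(1))), tolerance = 1e-10)
  }
})

test_that("compute_msd equals the O(N^2) definition and closed forms", {
  # stationary track: msd identically 0
  still <- structure(list(track_id = "s", points = data.frame(
    frame = 0:19, x = 1, y = 2, z = 3, intensity = 1)), class = "trajectory3d")
  expect_true(all(compute_msd(still, dt = 0.032)$msd == 0))

  # ballistic motion: msd(tau) = (v tau)^2
  v <- 0.7; dt <- 0.05
  ball <- structure(list(track_id = "b", points = data.frame(
    frame = 0:39, x = v * dt * (0:39), y = 0, z = 0, intensity = 1)),
    class = "trajectory3d")
  m <- compute_msd(ball, dt = dt)
  expect_equal(m$msd, (v * m$lags)^2, tolerance = 1e-10)

  # random track: exact agreement with the double-loop oracle
  set.seed(17)
  r <- apply(matrix(rnorm(3 * 60, sd = 0.1), 60, 3), 2, cumsum)
  tr <- structure(list(track_id = "r", points = data.frame(
    frame = 0:59, x = r[, 1], y = r[, 2], z = r[, 3], intensity = 1)),
    class = "trajectory3d")
  m2 <- compute_msd(tr, dt = 0.032)
  expect_equal(m2$msd, oracle_msd_loops(r, length(m2$lags)), tolerance = 1e-12)

  short <- structure(list(track_id = "x", points = data.frame(
    frame = 0:5, x = 0, y = 0, z = 0, intensity = 1)), class = "trajectory3d")
  expect_error(compute_msd(short), class = "track_too_short")
})

test_that("anomalous fit is exact on exact data and covariant under scaling", {
  tau <- (1:20) * 0.032
  msd <- 6 * 0.8 * tau
  f <- fit_anomalous(tau, msd)
  expect_equal(f$D, 0.8, tolerance = 1e-5)
  expect_equal(f$alpha, 1, tolerance = 1e-5)
  expect_equal(f$offset, 0, tolerance = 1e-8)

  # doubling the MSD doubles D, alpha unchanged
  f2 <- fit_anomalous(tau, 2 * msd)
  expect_equal(f2$D, 2 * f$D, tolerance = 1e-5)
  expect_equal(f2$alpha, f$alpha, tolerance = 1e-5)

  # subdiffusive exact data with a known offset
  msd3 <- 6 * 1.2 * tau^0.9 + 6 * 0.02^2
  f3 <- fit_anomalous(tau, msd3)
  expect_equal(f3$D, 1.2, tolerance = 1e-3)
  expect_equal(f3$alpha, 0.9, tolerance = 1e-3)

  expect_error(fit_anomalous(tau[1:3], msd[1:3]), class = "invalid_input")
})

test_that("per-track fits over an ensemble recover (D, alpha) within stochastic tolerance", {
  cfg <- spt_sim_config(D_true = 1.2, alpha = 0.9, n_particles = 200,
                        n_frames = 300, loc_sd = 20, seed = 23)
  tracks <- simulate_fbm_tracks(cfg)
  fits <- fit_tracks_msd(tracks, dt = cfg$dt)
  D <- vapply(fits, function(f) f$D, numeric(1))
  a <- vapply(fits, function(f) f$alpha, numeric(1))
  expect_lt(abs(median(D) - 1.2) / 1.2, 0.10)
  expect_lt(abs(median(a) - 0.9), 0.05)
  # independent oracle: log-log regression on the ensemble-averaged MSD
  msds <- sapply(tracks, function(t)
    compute_msd(t, dt = cfg$dt, max_lag_fraction = 0.05)$msd)
  em <- rowMeans(msds) - 6 * (cfg$loc_sd / 1000)^2
  lags <- seq_along(em) * cfg$dt
  cf <- coef(lm(log(em) ~ log(lags)))
  expect_lt(abs(exp(cf[[1]]) / 6 - 1.2) / 1.2, 0.10)
  expect_lt(abs(cf[[2]] - 0.9), 0.05)
})

test_that("diffusion summaries pool D with closed-form SEM", {
  mk <- function(D) structure(list(D = D, alpha = 1, D_app = D,
                                   converged = TRUE), class = "msd_fit")
  s <- summarize_diffusion(lapply(c(0.7, 0.8, 0.9), mk), "nt")
  expect_equal(s$D_mean, 0.8)
  expect_equal(s$D_sem, sd(c(0.7, 0.8, 0.9)) / sqrt(3))
  expect_equal(s$D_sem, 0.0577, tolerance = 1e-3)

  one <- summarize_diffusion(list(mk(0.8)), "single")
  expect_false(one$sem_defined)
  expect_true(is.na(one$D_sem))

  bad <- structure(list(D = NA, converged = FALSE), class = "msd_fit")
  expect_error(summarize_diffusion(list(bad)), class = "empty_input")
})

test_that("plane calibrations round-trip through YAML", {
  set.seed(5)
  cal <- plane_calibration(
    lapply(1:9, function(j) cbind(matrix(c(1, 0, 0, 1) + rnorm(4, 0, 0.01),
                                         2, 2), runif(2, -3, 3))),
    spacing = 400, efficiencies = runif(9, 0.9, 1.1))
  path <- tempfile(fileext = ".yml")
  write_plane_calibration(cal, path)
  back <- read_plane_calibration(path)
  expect_equal(back$spacing, cal$spacing)
  expect_equal(back$efficiencies, cal$efficiencies, tolerance = 1e-9)
  for (j in 1:9) expect_equal(back$transforms[[j]], cal$transforms[[j]],
                              tolerance = 1e-9)
  unlink(path)
})
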