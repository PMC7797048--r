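# AFM force-curve analysis: raw z-sensor / deflection records are converted
# to force-indentation curves, the contact point is located by piecewise
# model selection, and the effective Young's modulus is obtained from the
# pyramidal-tip Hertz relation F = C * E/(1-nu^2) * tan(theta) * delta^2.

#' Construct an AFM force curve record
#'
#' @param z_sensor Z-piezo positions (nm), monotone within the segment;
#'   larger z means the tip is driven further toward the sample.
#' @param deflection Cantilever deflection (nm), same length as `z_sensor`.
#' @param k Cantilever spring constant (pN/nm).
#' @param segment `"approach"` or `"retract"`.
#' @param id Curve label.
#' @return List of class `force_curve`.
#' @export
force_curve <- function(z_sensor, deflection, k, segment = "approach",
                        id = "curve") {
  if (length(z_sensor) != length(deflection))
    nm_stop("z_sensor and deflection must have equal length", "invalid_input")
  if (length(z_sensor) < 50L)
    nm_stop("force curve needs at least 50 samples", "invalid_input")
  check_scalar(k, "k", positive = TRUE)
  dz <- diff(z_sensor)
  if (!(all(dz >= 0) || all(dz <= 0)))
    nm_stop("z_sensor must be monotone within a segment", "invalid_input")
  segment <- match.arg(segment, c("approach", "retract"))
  structure(list(z_sensor = as.numeric(z_sensor),
                 deflection = as.numeric(deflection),
                 k = k, segment = segment, id = as.character(id)),
            class = "force_curve")
}

#' Baseline deflection of a curve (median of the first 20% of samples)
#' @noRd
.baseline_d0 <- function(curve, frac = 0.2) {
  n0 <- max(1L, floor(frac * length(curve$deflection)))
  stats::median(curve$deflection[seq_len(n0)])
}

#' Convert a force curve to force vs indentation
#'
#' Given a contact point `z0`, computes force F = k * (d - d0) (pN converted
#' to nN) and tip-sample indentation delta = (z - z0) - (d - d0), where `d0`
#' is the pre-contact baseline deflection (median of the first 20% of the
#' curve). Cantilever bending is thereby subtracted from the piezo travel.
#' Only samples with delta > 0 are retained.
#'
#' @param curve A [force_curve()].
#' @param z0 Contact point (nm), within the curve's z range.
#' @param d0 Baseline deflection (nm); default estimated from the curve.
#' @return List with `delta` (nm), `force` (nN) and the `d0` used.
#' @export
to_force_indentation <- function(curve, z0, d0 = NULL) {
  stopifnot(inherits(curve, "force_curve"))
  check_scalar(z0, "z0")
  if (z0 < min(curve$z_sensor) || z0 > max(curve$z_sensor))
    nm_stop("z0 outside the curve z range", "invalid_input")
  if (is.null(d0)) d0 <- .baseline_d0(curve)
  drel <- curve$deflection - d0
  delta <- (curve$z_sensor - z0) - drel
  keep <- delta > 0 & (curve$z_sensor > z0)
  if (!any(keep) || all(drel[keep] <= 0))
    nm_stop("no deflecting samples beyond the contact point", "empty_contact")
  list(delta = delta[keep], force = curve$k * drel[keep] / 1000, d0 = d0)
}

#' Closed-form Hertz modulus for given (delta, force) pairs
#'
#' The pyramidal Hertz law is linear in E/(1-nu^2), so the least-squares
#' modulus given the contact point is s = sum(F * delta^2) / sum(delta^4)
#' rescaled to Pa.
#' @noRd
.hertz_E_hat <- function(delta, force, nu, theta, C) {
  s <- sum(force * delta^2) / sum(delta^4)     # nN / nm^2
  s * 1e9 * (1 - nu^2) / (C * tan(theta))
}

#' Fit the pyramidal-tip Hertz model to a force-indentation curve
#'
#' Least-squares fit of F = C * E/(1-nu^2) * tan(theta) * delta^2 with the
#' Bilodeau four-sided-pyramid prefactor C = 0.7453 (set `C = 0.5` for the
#' Sneddon cone form). Because the model is linear in E/(1-nu^2), the
#' modulus is obtained in closed form.
#'
#' @param delta Indentation depths (nm), >= 0.
#' @param force Forces (nN), same length.
#' @param nu Poisson ratio (default 0.5, incompressible).
#' @param theta Pyramid face half-angle (radians; default 17.5 degrees).
#' @param C Indenter prefactor.
#' @param z0 Contact point to record in the result (nm), optional.
#' @return List of class `hertz_fit` with fields `z0`, `E` (Pa), `nu`,
#'   `theta`, `rss`, `fit_range` (nm), `n`, `converged`.
#' @export
fit_hertz_pyramid <- function(delta, force, nu = 0.5, theta = 17.5 * pi / 180,
                              C = .C_PYR, z0 = NA_real_) {
  if (length(delta) != length(force))
    nm_stop("delta and force must have equal length", "invalid_input")
  if (length(delta) < 10L)
    nm_stop("need at least 10 post-contact samples", "invalid_input")
  if (any(delta < 0))
    nm_stop("indentation depths must be >= 0", "invalid_input")
  if (max(delta) - min(delta) < .Machine$double.eps^0.5 * max(delta, 1))
    nm_stop("degenerate indentation range", "singular_fit")
  E <- .hertz_E_hat(delta, force, nu, theta, C)
  resid <- force - hertz_force(delta, E, nu, theta, C)
  structure(list(z0 = z0, E = E, nu = nu, theta = theta,
                 rss = sum(resid^2), fit_range = range(delta),
                 n = length(delta), converged = is.finite(E) && E > 0),
            class = "hertz_fit")
}

#' SSE of the piecewise baseline + Hertz model for one candidate contact point
#' @noRd
.contact_sse <- function(curve, z0, d0, nu, theta, C, F_max) {
  z <- curve$z_sensor; drel <- curve$deflection - d0
  pre <- z <= z0
  sse <- sum(drel[pre]^2)
  post <- which(!pre)
  if (length(post) < 2L) return(list(sse = Inf, E = NA_real_))
  delta <- (z[post] - z0) - drel[post]
  force <- curve$k * drel[post] / 1000
  ok <- delta > 0
  if (!is.null(F_max)) {
    over <- which(force > F_max)
    if (length(over) > 0L) ok[seq_along(ok) >= min(over) + 1L] <- FALSE
  }
  if (sum(ok) < 2L) return(list(sse = Inf, E = NA_real_))
  delta <- delta[ok]; force <- force[ok]
  E <- .hertz_E_hat(delta, force, nu, theta, C)
  if (!is.finite(E) || E <= 0) return(list(sse = Inf, E = NA_real_))
  resid_d <- (force - hertz_force(delta, E, nu, theta, C)) * 1000 / curve$k
  # samples past contact but excluded (delta <= 0) count as baseline residuals
  excl <- post[!ok & ((z[post] - z0) - drel[post]) <= 0]
  list(sse = sse + sum(resid_d^2) + sum(drel[excl]^2), E = E)
}

#' Locate the tip-sample contact point of an approach curve
#'
#' Deterministic piecewise model selection: for each candidate contact point
#' the curve is modelled as a flat baseline before contact plus a Hertzian
#' rise after it (modulus refit in closed form per candidate), and the
#' candidate minimising the total squared deflection residual is returned.
#' A coarse scan over every `stride`-th sample position is refined by an
#' exhaustive local scan, then by golden-section search between neighbouring
#' samples.
#'
#' @param curve A [force_curve()] (approach segment).
#' @param nu,theta,C Hertz-model parameters used during scoring.
#' @param F_max Force cap limiting the fit window (nN); NULL to use all
#'   post-contact samples.
#' @param stride Coarse-scan stride in samples.
#' @param min_baseline Minimum number of pre-contact baseline samples.
#' @return Contact point z0 (nm).
#' @export
find_contact_point <- function(curve, nu = 0.5, theta = 17.5 * pi / 180,
                               C = .C_PYR, F_max = NULL, stride = 8L,
                               min_baseline = 20L) {
  stopifnot(inherits(curve, "force_curve"))
  n <- length(curve$z_sensor)
  if (min_baseline < 1L || n - min_baseline < 12L)
    nm_stop("curve too short for contact search", "invalid_input")
  d0 <- .baseline_d0(curve)
  idx_lo <- min_baseline
  idx_hi <- n - 12L
  cand <- unique(c(seq(idx_lo, idx_hi, by = as.integer(stride)), idx_hi))
  score <- vapply(cand, function(i)
    .contact_sse(curve, curve$z_sensor[i], d0, nu, theta, C, F_max)$sse,
    numeric(1))
  if (!any(is.finite(score)))
    nm_stop("no candidate contact point admits a Hertzian fit", "no_contact")
  best <- cand[which.min(score)]
  # local exhaustive refinement at sample resolution
  local <- max(idx_lo, best - as.integer(stride)):min(idx_hi, best + as.integer(stride))
  score2 <- vapply(local, function(i)
    .contact_sse(curve, curve$z_sensor[i], d0, nu, theta, C, F_max)$sse,
    numeric(1))
  best <- local[which.min(score2)]
  # reject if the piecewise model is no better than baseline-only
  sse_base <- sum((curve$deflection - d0)^2)
  sse_best <- min(score2)
  if (!is.finite(sse_best) || sse_best >= sse_base)
    nm_stop("no contact detected: baseline-only model fits best", "no_contact")
  # golden-section refinement between neighbouring samples
  lo <- curve$z_sensor[max(best - 1L, idx_lo)]
  hi <- curve$z_sensor[min(best + 1L, idx_hi)]
  f <- function(z0) .contact_sse(curve, z0, d0, nu, theta, C, F_max)$sse
  opt <- stats::optimize(f, interval = c(lo, hi), tol = 1e-3)
  if (opt$objective <= sse_best) opt$minimum else curve$z_sensor[best]
}

#' Analyse one raw approach curve end to end
#'
#' Convenience wrapper: contact detection, force-indentation conversion with
#' the fit window capped at `F_max`, and the pyramidal Hertz fit.
#'
#' @inheritParams find_contact_point
#' @param F_max Force cap for the fit window (nN).
#' @return A `hertz_fit` (with `converged = FALSE` and `E = NA` if contact
#'   detection or fitting fails).
#' @export
analyze_force_curve <- function(curve, nu = 0.5, theta = 17.5 * pi / 180,
                                C = .C_PYR, F_max = 1.5, stride = 8L) {
  res <- tryCatch({
    z0 <- find_contact_point(curve, nu, theta, C, F_max, stride)
    fi <- to_force_indentation(curve, z0)
    keep <- if (is.null(F_max)) fi$force > 0 else fi$force <= F_max & fi$force > 0
    if (sum(keep) < 10L) keep <- if (is.null(F_max)) rep(TRUE, length(fi$force))
    else fi$force <= F_max
    fit_hertz_pyramid(fi$delta[keep], fi$force[keep], nu, theta, C, z0 = z0)
  }, nucmech_error = function(e) {
    structure(list(z0 = NA_real_, E = NA_real_, nu = nu, theta = theta,
                   rss = NA_real_, fit_range = c(NA_real_, NA_real_),
                   n = 0L, converged = FALSE, error = conditionMessage(e)),
              class = "hertz_fit")
  })
  res$id <- curve$id
  res
}

#' Calibrate a cantilever spring constant by the thermal method
#'
#' Removes DC offset and linear drift from a thermal deflection series,
#' obtains the deflection variance from the integrated one-sided power
#' spectrum (DC bin excluded), and applies the first-flexural-mode
#' correction: k = beta * kB * T / <d^2> with beta = 0.817.
#'
#' @param thermal Deflection series (nm), length >= 1e4.
#' @param T Temperature (K).
#' @param beta Mode-correction factor.
#' @return Spring constant (pN/nm).
#' @export
calibrate_spring_constant <- function(thermal, T = 295, beta = 0.817) {
  if (length(thermal) < 1e4)
    nm_stop("thermal series must have at least 1e4 samples", "invalid_input")
  check_scalar(T, "T", positive = TRUE)
  n <- length(thermal)
  t_idx <- seq_len(n)
  x <- stats::residuals(stats::lm(thermal ~ t_idx))  # DC + drift removal
  pw <- Mod(stats::fft(x))^2 / n^2
  pw[1] <- 0                                         # DC excluded
  var_nm2 <- sum(pw)                                 # Parseval: total variance
  if (var_nm2 <= 0)
    nm_stop("non-positive deflection variance", "invalid_input")
  # k[N/m] = beta * kB*T / <d^2>[m^2]; pN/nm = 1e-3 N/m
  beta * .kB * T / (var_nm2 * 1e-18) * 1e3
}

#' Aggregate per-point Hertz fits into a per-cell stiffness
#'
#' Per-cell modulus is the arithmetic mean over converged point fits
#' (convention: each cell is probed at ~10 locations and averaged).
#' Non-converged fits are excluded and counted.
#'
#' @param point_fits List of `hertz_fit` objects for one cell.
#' @param cell_id Cell label.
#' @return List of class `cell_stiffness` with `cell_id`, `point_moduli`
#'   (Pa), `E_mean` (Pa), `n_points`, `excluded_count`.
#' @export
aggregate_cell <- function(point_fits, cell_id = "cell") {
  if (length(point_fits) == 0L)
    nm_stop("no point fits supplied", "empty_cell")
  conv <- vapply(point_fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(conv))
    nm_stop("no converged fits for this cell", "empty_cell")
  E <- vapply(point_fits[conv], function(f) f$E, numeric(1))
  structure(list(cell_id = as.character(cell_id), point_moduli = E,
                 E_mean = mean(E), n_points = length(E),
                 excluded_count = sum(!conv)),
            class = "cell_stiffness")
}

#' Run the AFM pipeline over a batch of cells
#'
#' @param curves_by_cell Named list; each element is a list of
#'   [force_curve()]s belonging to one cell.
#' @param ... Passed to [analyze_force_curve()].
#' @return data.frame with one row per cell: `cell_id`, `n_points`,
#'   `excluded`, `E_mean_Pa`.
#' @export
afm_batch <- function(curves_by_cell, ...) {
  stopifnot(is.list(curves_by_cell), !is.null(names(curves_by_cell)))
  rows <- lapply(names(curves_by_cell), function(cid) {
    fits <- lapply(curves_by_cell[[cid]], analyze_force_curve, ...)
    cs <- aggregate_cell(fits, cid)
    data.frame(cell_id = cid, n_points = cs$n_points,
               excluded = cs$excluded_count, E_mean_Pa = cs$E_mean,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a force curve to a two-column text file
#'
#' Format: `# key = value` header lines (spring_constant pN/nm, segment, id)
#' followed by whitespace-delimited `z_sensor_nm deflection_nm` columns.
#'
#' @param curve A [force_curve()].
#' @param path Output file path.
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# spring_constant = %.6g", curve$k),
               sprintf("# segment = %s", curve$segment),
               sprintf("# id = %s", curve$id),
               "# z_sensor_nm deflection_nm"), con)
  utils::write.table(data.frame(curve$z_sensor, curve$deflection), con,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a force curve written by [write_force_curve()]
#'
#' @param path File path.
#' @return A [force_curve()].
#' @export
read_force_curve <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_key <- function(key) {
    m <- grep(sprintf("^#\\s*%s\\s*=", key), hdr, value = TRUE)
    if (length(m) == 0L) return(NA_character_)
    trimws(sub(".*=", "", m[1]))
  }
  k <- as.numeric(get_key("spring_constant"))
  segment <- get_key("segment")
  id <- get_key("id")
  dat <- utils::read.table(text = lines[!grepl("^#", lines)])
  force_curve(dat[[1]], dat[[2]], k = k,
              segment = if (is.na(segment)) "approach" else segment,
              id = if (is.na(id)) basename(path) else id)
}
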