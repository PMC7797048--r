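# Independent oracle implementations used to cross-check the package's
# estimators. These deliberately use brute-force / closed-form routes that
# share no code with the implementation under test.

# Exhaustive grid search over (z0, E) minimising the deflection SSE of the
# piecewise baseline+Hertz model; E profiled on a dense grid (not in closed
# form, to stay independent of the implementation).
oracle_grid_hertz <- function(curve, E_grid, nu = 0.5,
                              theta = 17.5 * pi / 180, C = 0.7453) {
  z <- curve$z_sensor
  d0 <- median(curve$deflection[seq_len(floor(0.2 * length(z)))])
  drel <- curve$deflection - d0
  best <- list(sse = Inf, z0 = NA, E = NA)
  for (i in 21:(length(z) - 12)) {
    z0 <- z[i]
    pre <- z <= z0
    sse_base <- sum(drel[pre]^2)
    post <- which(!pre)
    delta <- (z[post] - z0) - drel[post]
    ok <- delta > 0
    if (sum(ok) < 2) next
    F_obs <- curve$k * drel[post][ok] / 1000
    for (E in E_grid) {
      F_mod <- C * (E / (1 - nu^2)) * tan(theta) * delta[ok]^2 * 1e-9
      sse <- sse_base + sum(((F_obs - F_mod) * 1000 / curve$k)^2) +
        sum(drel[post][!ok]^2)
      if (sse < best$sse) best <- list(sse = sse, z0 = z0, E = E)
    }
  }
  best
}

# O(N^2) double-loop time-averaged MSD.
oracle_msd_loops <- function(r, max_lag) {
  N <- nrow(r)
  sapply(seq_len(max_lag), function(n) {
    acc <- 0
    for (i in 1:(N - n)) acc <- acc + sum((r[i + n, ] - r[i, ])^2)
    acc / (N - n)
  })
}

# Brute-force frame-to-frame linking for <= 3 particles: enumerate every
# matching between consecutive-frame detections, maximise links then
# minimise total squared displacement.
oracle_link_bruteforce <- function(locs, max_disp_nm, min_len) {
  max_d <- max_disp_nm / 1000
  frames <- sort(unique(locs$frame))
  tracks <- list()
  open <- list()   # each: list(rows = data.frame, last_frame)
  for (fr in frames) {
    det <- locs[locs$frame == fr, , drop = FALSE]
    prev_ok <- which(vapply(open, function(o) o$last_frame == fr - 1, logical(1)))
    nd <- nrow(det); np <- length(prev_ok)
    best <- NULL
    # enumerate assignments of detections to open tracks (or none)
    choices <- rep(list(c(NA, prev_ok)), nd)
    grid <- do.call(expand.grid, choices)
    for (g in seq_len(max(nrow(grid), 1))) {
      asg <- if (nd > 0) unlist(grid[g, ]) else integer(0)
      used <- asg[!is.na(asg)]
      if (anyDuplicated(used)) next
      cost <- 0; valid <- TRUE
      for (i in seq_len(nd)) {
        if (is.na(asg[i])) next
        o <- open[[asg[i]]]
        last <- o$rows[nrow(o$rows), ]
        d <- sqrt((det$x[i] - last$x)^2 + (det$y[i] - last$y)^2 +
                    (det$z[i] - last$z)^2)
        if (d > max_d) { valid <- FALSE; break }
        cost <- cost + d^2
      }
      if (!valid) next
      nlinks <- sum(!is.na(asg))
      if (is.null(best) || nlinks > best$nlinks ||
          (nlinks == best$nlinks && cost < best$cost))
        best <- list(asg = asg, nlinks = nlinks, cost = cost)
    }
    asg <- if (is.null(best)) rep(NA_integer_, nd) else best$asg
    new_open <- list()
    extended <- logical(length(open))
    for (i in seq_len(nd)) {
      row <- det[i, c("frame", "x", "y", "z")]
      if (!is.na(asg[i])) {
        extended[asg[i]] <- TRUE
        new_open[[length(new_open) + 1]] <-
          list(rows = rbind(open[[asg[i]]]$rows, row), last_frame = fr)
      } else {
        new_open[[length(new_open) + 1]] <- list(rows = row, last_frame = fr)
      }
    }
    for (j in seq_along(open))
      if (!extended[j]) tracks[[length(tracks) + 1]] <- open[[j]]$rows
    open <- new_open
  }
  for (o in open) tracks[[length(tracks) + 1]] <- o$rows
  Filter(function(t) nrow(t) >= min_len, tracks)
}

# Two-tailed p for a t statistic by numeric integration of the t density.
oracle_t_pvalue <- function(tval, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * integrate(dens, abs(tval), Inf, rel.tol = 1e-10)$value
}

# Otsu by direct exhaustive between-class variance maximisation over
# candidate thresholds (midpoints between sorted unique values, capped).
oracle_otsu <- function(values) {
  u <- sort(unique(values))
  if (length(u) > 512) u <- quantile(values, seq(0, 1, length.out = 512))
  cands <- (head(u, -1) + tail(u, -1)) / 2
  bcv <- sapply(cands, function(t) {
    lo <- values[values <= t]; hi <- values[values > t]
    if (length(lo) == 0 || length(hi) == 0) return(-Inf)
    w0 <- length(lo) / length(values)
    w0 * (1 - w0) * (mean(lo) - mean(hi))^2
  })
  cands[which.max(bcv)]
}
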