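# Synthetic AFM data: Hertzian approach curves with a hidden contact point,
# and thermally driven cantilever deflection series for spring-constant
# calibration. Ground truth is attached so recovery can be tested.

#' Configuration for synthetic AFM force curves
#'
#' Defaults mirror the instrument settings of the study being emulated:
#' a triangular cantilever carrying a four-sided pyramidal tip with a 35
#' degree opening angle (face half-angle 17.5 degrees), spring constant
#' around 30 pN/nm, indentation driven up to a 1.5 nN force cap, with about
#' 1 nm RMS deflection noise.
#'
#' @param E_true Ground-truth effective Young's modulus (Pa).
#' @param nu Poisson ratio; 0.5 treats the sample as incompressible.
#' @param theta Pyramid face half-angle (radians).
#' @param k Cantilever spring constant (pN/nm).
#' @param z_range Z-piezo scan length (nm).
#' @param n_points Samples per curve.
#' @param noise_sd Deflection noise RMS (nm).
#' @param F_max Force cap terminating the approach (nN).
#' @param z0 Contact point position along the scan (nm). Default places it at
#'   one third of the scan so a long baseline precedes contact.
#' @param seed RNG seed for the noise draw (NULL = use current RNG state).
#' @return List of class `afm_sim_config`.
#' @export
afm_sim_config <- function(E_true = 4400, nu = 0.5, theta = 17.5 * pi / 180,
                           k = 30, z_range = 6000, n_points = 1200,
                           noise_sd = 1, F_max = 1.5, z0 = z_range / 3,
                           seed = NULL) {
  check_scalar(E_true, "E_true", positive = TRUE)
  check_scalar(nu, "nu")
  if (nu < 0 || nu > 0.5) nm_stop("'nu' must lie in [0, 0.5]", "invalid_config")
  check_scalar(theta, "theta", positive = TRUE)
  if (theta >= pi / 2) nm_stop("'theta' must be < pi/2", "invalid_config")
  check_scalar(k, "k", positive = TRUE)
  check_scalar(z_range, "z_range", positive = TRUE)
  check_scalar(n_points, "n_points", positive = TRUE)
  if (n_points < 50) nm_stop("'n_points' must be >= 50", "invalid_config")
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(F_max, "F_max", positive = TRUE)
  check_scalar(z0, "z0")
  if (z0 <= 0 || z0 >= z_range)
    nm_stop("'z0' must lie inside the scan range", "invalid_config")
  structure(list(E_true = E_true, nu = nu, theta = theta, k = k,
                 z_range = z_range, n_points = as.integer(n_points),
                 noise_sd = noise_sd, F_max = F_max, z0 = z0, seed = seed),
            class = "afm_sim_config")
}

# Hertz prefactor for a four-sided pyramidal indenter (Bilodeau form).
.C_PYR <- 0.7453

#' Hertz force law for a pyramidal tip
#'
#' Force (nN) at indentation depth delta (nm) for a rigid four-sided pyramid
#' pressing an elastic half-space: F = C * E/(1 - nu^2) * tan(theta) * delta^2
#' with C = 0.7453. Setting `C = 0.5` recovers the Sneddon cone form
#' 0.5 * tan(theta) (exposed because "modified Hertz" conventions vary).
#'
#' @param delta Indentation depth (nm), >= 0.
#' @param E Effective Young's modulus (Pa).
#' @param nu Poisson ratio.
#' @param theta Face half-angle (radians).
#' @param C Indenter-geometry prefactor (default Bilodeau pyramid).
#' @return Force in nN.
#' @export
hertz_force <- function(delta, E, nu = 0.5, theta = 17.5 * pi / 180,
                        C = .C_PYR) {
  # F[N] = C * E/(1-nu^2) * tan(theta) * (delta[m])^2; with delta in nm and
  # F in nN the conversion factor is 1e-18 * 1e9 = 1e-9.
  C * (E / (1 - nu^2)) * tan(theta) * delta^2 * 1e-9
}

#' Simulate one AFM approach curve
#'
#' Generates a z-sensor vs deflection record: flat (noisy) baseline before the
#' hidden contact point `z0`, and beyond it a deflection solving the implicit
#' contact condition k*d = C * E/(1-nu^2) * tan(theta) * delta^2 with
#' delta = (z - z0) - d, i.e. cantilever bending is subtracted from the piezo
#' travel self-consistently at every sample. The curve is truncated where the
#' force exceeds `F_max` (the instrument's indentation force cap). Gaussian
#' deflection noise is added after solving.
#'
#' @param cfg An [afm_sim_config()].
#' @param id Curve label.
#' @return A [force_curve()] with attribute `truth`, a list holding the
#'   generating `z0` (nm), `E` (Pa) and configuration.
#' @export
simulate_force_curve <- function(cfg, id = "sim") {
  stopifnot(inherits(cfg, "afm_sim_config"))
  z <- seq(0, cfg$z_range, length.out = cfg$n_points)
  s <- z - cfg$z0                         # piezo travel past contact (nm)
  d <- numeric(length(z))
  post <- s > 0
  if (any(post)) {
    # k*d = A*u^2 with u = s - d  =>  A u^2 + k u - k s = 0, keep the
    # positive root. A in pN/nm^2, k in pN/nm, u and s in nm.
    A <- .C_PYR * (cfg$E_true / (1 - cfg$nu^2)) * tan(cfg$theta) * 1e-6
    sp <- s[post]
    u <- (-cfg$k + sqrt(cfg$k^2 + 4 * A * cfg$k * sp)) / (2 * A)
    d[post] <- sp - u
  }
  # truncate where the force cap is exceeded (keep first crossing sample)
  F_pN <- cfg$k * d
  over <- which(F_pN > cfg$F_max * 1000)
  keep <- if (length(over) > 0L) seq_len(min(over)) else seq_along(z)
  z <- z[keep]; d <- d[keep]
  if (cfg$noise_sd > 0) {
    d <- d + with_seed(cfg$seed, rnorm(length(d), sd = cfg$noise_sd))
  }
  fc <- force_curve(z_sensor = z, deflection = d, k = cfg$k,
                    segment = "approach", id = id)
  attr(fc, "truth") <- list(z0 = cfg$z0, E = cfg$E_true, config = cfg)
  fc
}

#' Simulate a thermally driven cantilever deflection series
#'
#' Produces the measured (optical-lever) deflection of the first flexural
#' mode of a cantilever in thermal equilibrium, modelled as a simple harmonic
#' oscillator spectrum sampled at `fs`. The apparent variance of the series
#' is `beta * kB * T / k` where `beta = 0.817` is the standard first-mode
#' correction relating measured first-mode deflection to the intrinsic
#' equipartition variance `kB * T / k`; [calibrate_spring_constant()] applies
#' the matching correction so the round trip recovers `k`. Set `beta = 1` to
#' generate an ideal displacement record obeying equipartition exactly.
#'
#' Synthesis is exact in distribution: independent Gaussian Fourier
#' amplitudes with the harmonic-oscillator power profile
#' 1 / ((1 - (f/f0)^2)^2 + (f/(f0*Q))^2), normalised so the expected total
#' variance equals the target.
#'
#' @param k Spring constant (pN/nm).
#' @param T Temperature (K).
#' @param f0 Resonance frequency (Hz).
#' @param Q Quality factor.
#' @param n_samples Number of samples (>= 2).
#' @param fs Sampling rate (Hz).
#' @param beta First-mode measurement correction factor.
#' @param seed RNG seed.
#' @return Numeric vector of deflections (nm) with attribute `truth`
#'   (list with `k`, `T`, `fs`, `beta`, target variance in nm^2).
#' @export
simulate_thermal_spectrum <- function(k, T = 295, f0 = 10e3, Q = 2,
                                      n_samples = 2^17, fs = 100e3,
                                      beta = 0.817, seed = NULL) {
  check_scalar(k, "k", positive = TRUE)
  check_scalar(T, "T", nonneg = TRUE)
  check_scalar(f0, "f0", positive = TRUE)
  check_scalar(Q, "Q", positive = TRUE)
  check_scalar(fs, "fs", positive = TRUE)
  if (!is.numeric(n_samples) || n_samples < 2)
    nm_stop("'n_samples' must be >= 2", "invalid_config")
  n <- as.integer(n_samples)
  # target apparent variance in nm^2: beta * kB*T / k, with k in N/m = k_pNnm*1e-3
  target_var <- if (T == 0) 0 else beta * .kB * T / (k * 1e-3) * 1e18
  if (target_var == 0) {
    out <- numeric(n)
  } else {
    freqs <- seq(0, fs / 2, length.out = n %/% 2 + 1)
    S <- 1 / ((1 - (freqs / f0)^2)^2 + (freqs / (f0 * Q))^2)
    S[1] <- 0                          # no DC power
    out <- with_seed(seed, {
      # Hermitian-symmetric spectrum with Gaussian amplitudes
      nf <- length(freqs)
      re <- rnorm(nf) * sqrt(S / 2)
      im <- rnorm(nf) * sqrt(S / 2)
      im[1] <- 0
      if (n %% 2 == 0) { re[nf] <- re[nf] * sqrt(2); im[nf] <- 0 }
      spec <- complex(real = re, imaginary = im)
      full <- c(spec, Conj(rev(spec[2:(nf - (n %% 2 == 0))])))
      x <- Re(stats::fft(full, inverse = TRUE))
      # scale so that E[var] = target_var exactly
      expected_var <- 2 * sum(S) / n   # variance of x before scaling, /n^2*n
      x * sqrt(target_var / (expected_var * n))
    })
  }
  attr(out, "truth") <- list(k = k, T = T, fs = fs, beta = beta,
                             target_var_nm2 = target_var)
  out
}
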