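# Synthetic high-content-screening fields: Hoechst-stained elliptical nuclei
# with known areas, a gammaH2AX channel in which a known fraction of nuclei
# carries bright damage foci, and a decorative phalloidin channel.

#' Configuration for synthetic high-content screening fields
#'
#' Defaults emulate a 20x high-content scan of HeLa cells: ~180 um^2 nuclear
#' cross-sections with moderate spread, ~0.45 um pixels, and damaged nuclei
#' carrying 3-8 bright gammaH2AX foci.
#'
#' @param damaged_fraction_true Fraction of nuclei with foci, in \[0, 1\].
#'   Exactly `round(fraction * n)` nuclei per field are damaged
#'   (round-half-even).
#' @param n_nuclei_per_field Nuclei per field; scalar, or vector of length
#'   `n_fields`.
#' @param n_fields Number of fields.
#' @param nucleus_area_mean Mean nuclear cross-sectional area (um^2).
#' @param nucleus_area_sd SD of nuclear area (um^2).
#' @param pixel_size Pixel size (um/px).
#' @param foci_per_damaged_nucleus Integer range (length 2) of foci counts
#'   for damaged nuclei.
#' @param field_px Field side length (pixels); NULL = sized automatically so
#'   nuclei occupy about 20% of the field.
#' @param axis_ratio_range Range of ellipse axis ratios a/b.
#' @param seed RNG seed.
#' @return List of class `hcs_sim_config`.
#' @export
hcs_sim_config <- function(damaged_fraction_true = 0.05,
                           n_nuclei_per_field = 100L, n_fields = 20L,
                           nucleus_area_mean = 180, nucleus_area_sd = 40,
                           pixel_size = 0.454,
                           foci_per_damaged_nucleus = c(3L, 8L),
                           field_px = NULL, axis_ratio_range = c(1, 1.4),
                           seed = NULL) {
  check_scalar(damaged_fraction_true, "damaged_fraction_true")
  if (damaged_fraction_true < 0 || damaged_fraction_true > 1)
    nm_stop("'damaged_fraction_true' must lie in [0, 1]", "invalid_config")
  check_scalar(nucleus_area_mean, "nucleus_area_mean", positive = TRUE)
  check_scalar(nucleus_area_sd, "nucleus_area_sd", nonneg = TRUE)
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  check_scalar(n_fields, "n_fields", positive = TRUE)
  if (length(n_nuclei_per_field) == 1L)
    n_nuclei_per_field <- rep(as.integer(n_nuclei_per_field), n_fields)
  if (length(n_nuclei_per_field) != n_fields || any(n_nuclei_per_field < 1))
    nm_stop("'n_nuclei_per_field' must be scalar or one positive count per field",
            "invalid_config")
  if (length(foci_per_damaged_nucleus) != 2L ||
      any(foci_per_damaged_nucleus < 1) ||
      foci_per_damaged_nucleus[2] < foci_per_damaged_nucleus[1])
    nm_stop("'foci_per_damaged_nucleus' must be an increasing pair >= 1",
            "invalid_config")
  if (is.null(field_px)) {
    mean_px_area <- nucleus_area_mean / pixel_size^2
    field_px <- ceiling(sqrt(max(n_nuclei_per_field) * mean_px_area / 0.20))
  }
  structure(list(damaged_fraction_true = damaged_fraction_true,
                 n_nuclei_per_field = as.integer(n_nuclei_per_field),
                 n_fields = as.integer(n_fields),
                 nucleus_area_mean = nucleus_area_mean,
                 nucleus_area_sd = nucleus_area_sd,
                 pixel_size = pixel_size,
                 foci_per_damaged_nucleus = as.integer(foci_per_damaged_nucleus),
                 field_px = as.integer(field_px),
                 axis_ratio_range = axis_ratio_range, seed = seed),
            class = "hcs_sim_config")
}

#' Pixel mask of a rotated ellipse; returns index matrix rows (x, y)
#' @noRd
.ellipse_pixels <- function(cx, cy, a_px, b_px, phi, nx, ny) {
  r <- ceiling(max(a_px, b_px)) + 1L
  xs <- max(1L, floor(cx - r)):min(nx, ceiling(cx + r))
  ys <- max(1L, floor(cy - r)):min(ny, ceiling(cy + r))
  gx <- rep(xs, times = length(ys)) - cx
  gy <- rep(ys, each = length(xs)) - cy
  u <- gx * cos(phi) + gy * sin(phi)
  v <- -gx * sin(phi) + gy * cos(phi)
  inside <- (u / a_px)^2 + (v / b_px)^2 <= 1
  cbind(rep(xs, times = length(ys))[inside], rep(ys, each = length(xs))[inside])
}

#' Simulate high-content screening fields with known ground truth
#'
#' Each field contains non-overlapping elliptical nuclei whose areas are
#' drawn from a normal distribution (truncated at one quarter of the mean).
#' Exactly `round(damaged_fraction_true * n)` nuclei per field (round-half-
#' even) receive bright gammaH2AX foci, with the focus count drawn uniformly
#' from the configured range. The phalloidin channel is decorative smooth
#' background. Nuclei are placed by rejection sampling; if a nucleus cannot
#' be placed without overlap after bounded retries an error is raised.
#'
#' @param cfg An [hcs_sim_config()].
#' @return List of class `hcs_fields`: `fields` (list; per field a list with
#'   `hoechst`, `gh2ax`, `phalloidin` matrices), `truth` (data.frame with
#'   one row per nucleus: `field_id`, `nucleus_id`, `cx_px`, `cy_px`,
#'   `a_um`, `b_um`, `area_um2`, `damaged`, `foci`), and `cfg`.
#' @export
simulate_hcs_fields <- function(cfg) {
  stopifnot(inherits(cfg, "hcs_sim_config"))
  npx <- cfg$field_px
  px <- cfg$pixel_size
  out <- with_seed(cfg$seed, {
    fields <- vector("list", cfg$n_fields)
    truth <- vector("list", cfg$n_fields)
    for (f in seq_len(cfg$n_fields)) {
      n <- cfg$n_nuclei_per_field[f]
      n_damaged <- round(cfg$damaged_fraction_true * n)
      damaged <- rep(FALSE, n)
      if (n_damaged > 0) damaged[sample.int(n, n_damaged)] <- TRUE
      hoechst <- matrix(0.05, npx, npx)
      gh2ax <- matrix(0.02, npx, npx)
      centers <- matrix(numeric(0), 0, 2)
      radii <- numeric(0)
      rows <- vector("list", n)
      for (i in seq_len(n)) {
        area <- max(stats::rnorm(1, cfg$nucleus_area_mean, cfg$nucleus_area_sd),
                    cfg$nucleus_area_mean / 4)
        q <- stats::runif(1, cfg$axis_ratio_range[1], cfg$axis_ratio_range[2])
        a_um <- sqrt(area * q / pi); b_um <- a_um / q
        a_px <- a_um / px; b_px <- b_um / px
        r_eff <- max(a_px, b_px)
        phi <- stats::runif(1, 0, pi)
        placed <- FALSE
        for (try in seq_len(500L)) {
          cx <- stats::runif(1, r_eff + 2, npx - r_eff - 1)
          cy <- stats::runif(1, r_eff + 2, npx - r_eff - 1)
          if (nrow(centers) == 0L ||
              all((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2 >
                  (radii + r_eff + 3)^2)) { placed <- TRUE; break }
        }
        if (!placed)
          nm_stop("could not place a nucleus without overlap; reduce density",
                  "placement_failed")
        centers <- rbind(centers, c(cx, cy)); radii <- c(radii, r_eff)
        idx <- .ellipse_pixels(cx, cy, a_px, b_px, phi, npx, npx)
        hoechst[idx] <- stats::rnorm(1, 0.80, 0.04) +
          stats::rnorm(nrow(idx), 0, 0.03)
        gh2ax[idx] <- gh2ax[idx] + 0.03      # faint pan-nuclear background
        nf <- 0L
        if (damaged[i]) {
          nf <- sample(seq(cfg$foci_per_damaged_nucleus[1],
                           cfg$foci_per_damaged_nucleus[2]), 1L)
          fuv <- matrix(numeric(0), 0, 2)
          for (k in seq_len(nf)) {
            # focus inside the ellipse, away from the rim and other foci
            min_sep <- 4.5 / min(a_px, b_px)   # in unit-ellipse coordinates
            for (try in seq_len(200L)) {
              fu <- stats::runif(1, -0.75, 0.75); fv <- stats::runif(1, -0.75, 0.75)
              if (fu^2 + fv^2 > 0.75^2) next
              if (nrow(fuv) == 0L ||
                  all((fuv[, 1] - fu)^2 + (fuv[, 2] - fv)^2 > min_sep^2)) break
            }
            fuv <- rbind(fuv, c(fu, fv))
            fx <- cx + (fu * a_px) * cos(phi) - (fv * b_px) * sin(phi)
            fy <- cy + (fu * a_px) * sin(phi) + (fv * b_px) * cos(phi)
            sig <- 1.5
            wx <- max(1L, floor(fx - 5)):min(npx, ceiling(fx + 5))
            wy <- max(1L, floor(fy - 5)):min(npx, ceiling(fy + 5))
            spot <- 0.8 * outer(exp(-((wx - fx)^2) / (2 * sig^2)),
                                exp(-((wy - fy)^2) / (2 * sig^2)))
            gh2ax[wx, wy] <- gh2ax[wx, wy] + spot
          }
        }
        rows[[i]] <- data.frame(field_id = sprintf("field_%02d", f),
                                nucleus_id = i, cx_px = cx, cy_px = cy,
                                a_um = a_um, b_um = b_um,
                                area_um2 = pi * a_um * b_um,
                                damaged = damaged[i], foci = nf,
                                stringsAsFactors = FALSE)
      }
      hoechst <- pmin(pmax(hoechst + matrix(stats::rnorm(npx * npx, 0, 0.02),
                                            npx, npx), 0), 1.5)
      gh2ax <- pmax(gh2ax + matrix(stats::rnorm(npx * npx, 0, 0.01), npx, npx), 0)
      phalloidin <- .conv2_kernel(matrix(stats::runif(npx * npx, 0, 0.4),
                                         npx, npx), .gauss_kernel(4))
      fields[[f]] <- list(hoechst = hoechst, gh2ax = gh2ax,
                          phalloidin = phalloidin)
      truth[[f]] <- do.call(rbind, rows)
    }
    list(fields = fields, truth = do.call(rbind, truth))
  })
  structure(list(fields = out$fields, truth = out$truth, cfg = cfg),
            class = "hcs_fields")
}
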