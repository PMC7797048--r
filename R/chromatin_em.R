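# Chromatin condensation scoring from electron micrographs: dark
# (electron-dense, condensed) vs light (decondensed) pixel fractions inside
# a nuclear mask, with a matching two-phase blob-texture generator.

#' Configuration for synthetic EM micrographs
#'
#' @param condensed_fraction_true Target dark (condensed) area fraction
#'   inside the nuclear mask, in \[0, 1\].
#' @param blob_scale Texture correlation length (pixels).
#' @param contrast Grey-level separation between dark and light phases
#'   (image uses light = 0.7, dark = 0.7 - contrast).
#' @param noise_sd Additive Gaussian grey-level noise SD.
#' @param image_shape Integer vector (nx, ny) in pixels.
#' @param seed RNG seed.
#' @return List of class `em_sim_config`.
#' @export
em_sim_config <- function(condensed_fraction_true = 0.3, blob_scale = 6,
                          contrast = 0.4, noise_sd = 0.02,
                          image_shape = c(256L, 256L), seed = NULL) {
  check_scalar(condensed_fraction_true, "condensed_fraction_true")
  if (condensed_fraction_true < 0 || condensed_fraction_true > 1)
    nm_stop("'condensed_fraction_true' must lie in [0, 1]", "invalid_config")
  check_scalar(blob_scale, "blob_scale", positive = TRUE)
  check_scalar(contrast, "contrast", positive = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  if (length(image_shape) != 2L || any(image_shape < 32))
    nm_stop("'image_shape' must be two dimensions >= 32", "invalid_config")
  structure(list(condensed_fraction_true = condensed_fraction_true,
                 blob_scale = blob_scale, contrast = contrast,
                 noise_sd = noise_sd, image_shape = as.integer(image_shape),
                 seed = seed),
            class = "em_sim_config")
}

#' Simulate an EM micrograph of a nucleus with two-phase chromatin texture
#'
#' A smoothed Gaussian random field is thresholded at the quantile that makes
#' dark blobs cover exactly `condensed_fraction_true` of the elliptical
#' nuclear mask (to within one pixel). Dark pixels sit at grey level
#' 0.7 - contrast, light pixels at 0.7, outside-mask background at 0.9;
#' Gaussian noise is added on top.
#'
#' @param cfg An [em_sim_config()].
#' @return List of class `em_image`: `image` (matrix, grey levels), `mask`
#'   (logical matrix), and `truth` (list with `condensed_fraction` =
#'   realised ground-truth dark fraction, `dark_pixels`).
#' @export
simulate_em_image <- function(cfg) {
  stopifnot(inherits(cfg, "em_sim_config"))
  nx <- cfg$image_shape[1]; ny <- cfg$image_shape[2]
  xs <- (seq_len(nx) - (nx + 1) / 2) / (nx / 2)
  ys <- (seq_len(ny) - (ny + 1) / 2) / (ny / 2)
  mask <- outer(xs^2 / 0.85^2, ys^2 / 0.75^2, `+`) <= 1
  light <- 0.7; dark <- 0.7 - cfg$contrast; bg <- 0.9
  out <- with_seed(cfg$seed, {
    field <- matrix(rnorm(nx * ny), nx, ny)
    field <- .conv2_kernel(field, .gauss_kernel(cfg$blob_scale))
    inside <- field[mask]
    n_in <- length(inside)
    n_dark <- round(cfg$condensed_fraction_true * n_in)
    darksel <- matrix(FALSE, nx, ny)
    if (n_dark > 0) {
      thr <- sort(inside)[n_dark]
      darksel[mask] <- field[mask] <= thr
      # exact count despite ties
      if (sum(darksel) != n_dark) {
        idx <- which(mask & field <= thr)
        darksel[] <- FALSE
        darksel[idx[order(field[idx])][seq_len(n_dark)]] <- TRUE
      }
    }
    img <- matrix(bg, nx, ny)
    img[mask] <- light
    img[darksel] <- dark
    if (cfg$noise_sd > 0) img <- img + rnorm(nx * ny, sd = cfg$noise_sd)
    list(img = img, darksel = darksel, n_dark = sum(darksel), n_in = n_in)
  })
  structure(list(image = out$img, mask = mask,
                 truth = list(condensed_fraction = out$n_dark / out$n_in,
                              dark_pixels = out$darksel)),
            class = "em_image")
}

#' Otsu threshold of a grey-level sample (histogram form)
#'
#' Between-class-variance maximisation on a fixed-bin histogram of the
#' supplied pixel values; operates on in-mask pixels only, unlike
#' whole-image implementations.
#' @noRd
.otsu_masked <- function(values, levels = 256L) {
  rng <- range(values)
  if (diff(rng) == 0)
    nm_stop("constant image inside mask: Otsu threshold undefined",
            "degenerate_threshold")
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
                nbins = levels)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[levels]
  sb2 <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  sb2[!is.finite(sb2)] <- -Inf
  k <- which.max(sb2[-levels])
  breaks[k + 1L]
}

#' Quantify chromatin condensation inside a nuclear mask
#'
#' Thresholds the in-mask grey levels (per-image Otsu by default, or a fixed
#' value) and reports the dark (condensed) and light (decondensed) pixel
#' fractions. Pixels outside the mask never influence the threshold or the
#' fractions.
#'
#' @param image Grey-level matrix.
#' @param mask Logical matrix of the nuclear ROI, congruent with `image`.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold Fixed threshold (required when `threshold_method =
#'   "fixed"`).
#' @param bimodality_min Under Otsu, the split is accepted only when the
#'   separation of the two class means exceeds this multiple of the pooled
#'   within-class SD. An in-mask histogram failing the check is treated as
#'   single-phase nucleoplasm (condensed chromatin is defined by contrast
#'   against the nucleoplasm, so a single phase reads as decondensed:
#'   `dark_fraction = 0`, flagged `bimodal = FALSE`). A fully condensed
#'   nucleus with no light phase would be misread; that regime is outside
#'   the assay's working range.
#' @param image_id Label echoed in the result.
#' @return One-row data.frame (CondensationResult): `image_id`, `threshold`,
#'   `dark_fraction` (condensed), `light_fraction` (decondensed),
#'   `mask_area` (px), `bimodal`.
#' @export
quantify_condensation <- function(image, mask, threshold_method = c("otsu", "fixed"),
                                  threshold = NULL, bimodality_min = 4,
                                  image_id = "image") {
  threshold_method <- match.arg(threshold_method)
  if (!all(dim(image) == dim(mask)))
    nm_stop("image and mask must be congruent", "invalid_input")
  mask <- mask > 0
  if (!any(mask)) nm_stop("empty nuclear mask", "empty_mask")
  vals <- image[mask]
  bimodal <- TRUE
  if (threshold_method == "otsu") {
    thr <- .otsu_masked(vals)
    lo <- vals[vals <= thr]; hi <- vals[vals > thr]
    sw2 <- (sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)) / length(vals)
    if (sw2 > 0 && (mean(hi) - mean(lo)) < bimodality_min * sqrt(sw2)) {
      bimodal <- FALSE
      thr <- min(vals) - .Machine$double.eps
    }
  } else {
    check_scalar(threshold, "threshold")
    thr <- threshold
  }
  dark <- mean(vals <= thr)
  data.frame(image_id = as.character(image_id), threshold = thr,
             dark_fraction = dark, light_fraction = 1 - dark,
             mask_area = sum(mask), bimodal = bimodal,
             stringsAsFactors = FALSE)
}

#' Batch chromatin-condensation quantification with per-condition summaries
#'
#' @param images List of grey-level matrices (or `em_image` objects).
#' @param masks List of logical masks (ignored for `em_image` inputs, which
#'   carry their own).
#' @param conditions Character vector of condition labels, one per image.
#' @param threshold_method,threshold Passed to [quantify_condensation()].
#' @return List with `per_image` (one CondensationResult row per image, plus
#'   `condition`) and `summary` (per-condition n, mean and SEM of the dark
#'   and light fractions).
#' @export
batch_condensation <- function(images, masks = NULL, conditions,
                               threshold_method = "otsu", threshold = NULL) {
  if (length(images) == 0L) nm_stop("no images supplied", "empty_input")
  if (length(conditions) != length(images))
    nm_stop("one condition label per image is required", "invalid_input")
  rows <- lapply(seq_along(images), function(i) {
    im <- images[[i]]
    if (inherits(im, "em_image")) { msk <- im$mask; im <- im$image }
    else msk <- masks[[i]]
    r <- quantify_condensation(im, msk, threshold_method, threshold,
                               image_id = sprintf("img_%03d", i))
    r$condition <- as.character(conditions[i])
    r
  })
  per_image <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(unique(per_image$condition), function(cn) {
    d <- per_image[per_image$condition == cn, ]
    data.frame(condition = cn, n = nrow(d),
               dark_mean = mean(d$dark_fraction), dark_sem = sem(d$dark_fraction),
               light_mean = mean(d$light_fraction), light_sem = sem(d$light_fraction),
               stringsAsFactors = FALSE)
  }))
  list(per_image = per_image, summary = summ)
}
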