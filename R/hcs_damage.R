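# High-content damage screening: nuclei are segmented from the Hoechst
# channel, gammaH2AX signal and foci are measured per nucleus, nuclei are
# classified as damaged, and the percentage of damaged nuclei is summarised
# per field (the field/well is the replication unit, matching how such
# screens report n).

#' Segment nuclei from a Hoechst image
#'
#' Pipeline: Gaussian smoothing, Otsu threshold, hole filling, watershed
#' split of touching nuclei on the distance map, and an area filter in um^2.
#'
#' @param hoechst Single-channel image matrix.
#' @param pixel_size Pixel size (um/px).
#' @param blur_sigma Smoothing sigma (pixels).
#' @param min_area,max_area Area filter bounds (um^2).
#' @param watershed_tolerance Minimum distance-map depth separating two
#'   objects (pixels).
#' @return Integer label matrix (0 = background); an empty segmentation is
#'   returned as all zeros, not an error.
#' @export
segment_nuclei <- function(hoechst, pixel_size, blur_sigma = 2,
                           min_area = 40, max_area = 2500,
                           watershed_tolerance = 2) {
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  img <- EBImage::Image(pmin(pmax(hoechst, 0), 1))
  sm <- EBImage::gblur(img, sigma = blur_sigma)
  vals <- as.numeric(EBImage::imageData(sm))
  if (diff(range(vals)) == 0) return(matrix(0L, nrow(hoechst), ncol(hoechst)))
  thr <- .otsu_masked(vals)
  binary <- sm > thr
  binary <- EBImage::fillHull(binary)
  dm <- EBImage::distmap(binary)
  labels <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  lab <- matrix(as.integer(EBImage::imageData(labels)),
                nrow(hoechst), ncol(hoechst))
  # area filter, then relabel consecutively
  counts <- tabulate(lab[lab > 0])
  areas <- counts * pixel_size^2
  keep <- which(areas >= min_area & areas <= max_area)
  if (length(keep) == 0L) return(matrix(0L, nrow(hoechst), ncol(hoechst)))
  remap <- integer(length(counts))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0
  out[pos] <- remap[lab[pos]]
  out
}

#' Count gammaH2AX foci inside one nucleus mask
#'
#' Local maxima of the smoothed channel inside the mask whose prominence
#' over the nucleus median exceeds `min_prominence`.
#' @noRd
.count_foci <- function(sm, mask_idx, min_prominence, min_sep_px = 3) {
  vals <- sm[mask_idx]
  med <- stats::median(vals)
  nx <- nrow(sm); ny <- ncol(sm)
  cand <- mask_idx[sm[mask_idx] - med >= min_prominence, , drop = FALSE]
  if (nrow(cand) == 0L) return(0L)
  is_max <- vapply(seq_len(nrow(cand)), function(i) {
    ix <- cand[i, 1]; iy <- cand[i, 2]
    nb <- sm[max(1, ix - 1):min(nx, ix + 1), max(1, iy - 1):min(ny, iy + 1)]
    sm[ix, iy] >= max(nb)
  }, logical(1))
  cand <- cand[is_max, , drop = FALSE]
  if (nrow(cand) <= 1L) return(nrow(cand))
  # merge maxima closer than min_sep_px
  inten <- sm[cand]
  ord <- order(inten, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand) - 1L)) {
    if (!keep[i]) next
    later <- (i + 1):nrow(cand)
    d2 <- (cand[later, 1] - cand[i, 1])^2 + (cand[later, 2] - cand[i, 2])^2
    keep[later][d2 < min_sep_px^2] <- FALSE
  }
  sum(keep)
}

#' Measure per-nucleus area, gammaH2AX intensity and foci count
#'
#' Area is the pixel count times `pixel_size^2`. The mean gammaH2AX
#' intensity is background-corrected by the median of non-nucleus pixels of
#' the field. Foci are local maxima of the smoothed channel inside the mask
#' with prominence over the nucleus median above `foci_min_prominence`.
#'
#' @param labels Integer label matrix from [segment_nuclei()].
#' @param gh2ax gammaH2AX channel matrix, congruent with `labels`.
#' @param pixel_size Pixel size (um/px).
#' @param field_id Field label echoed per record.
#' @param foci_min_prominence Minimum focus prominence (intensity units).
#' @param foci_blur_sigma Smoothing applied before maxima detection (px).
#' @return data.frame (NucleusRecord rows): `nucleus_id`, `field_id`,
#'   `area` (um^2), `mean_gh2ax` (background-corrected), `foci_count`,
#'   `cx_px`, `cy_px`. The `damaged` flag is added by [classify_damaged()].
#' @export
measure_nuclei <- function(labels, gh2ax, pixel_size, field_id = "field",
                           foci_min_prominence = 0.2, foci_blur_sigma = 1) {
  if (!all(dim(labels) == dim(gh2ax)))
    nm_stop("labels and image must be congruent", "invalid_input")
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L)
    return(data.frame(nucleus_id = integer(), field_id = character(),
                      area = numeric(), mean_gh2ax = numeric(),
                      foci_count = integer(), cx_px = numeric(),
                      cy_px = numeric(), stringsAsFactors = FALSE))
  bg <- stats::median(gh2ax[labels == 0])
  sm <- if (foci_blur_sigma > 0)
    as.matrix(EBImage::gblur(EBImage::Image(gh2ax), sigma = foci_blur_sigma))
  else gh2ax
  rows <- lapply(ids, function(id) {
    mask_idx <- which(labels == id, arr.ind = TRUE)
    vals <- gh2ax[mask_idx]
    data.frame(nucleus_id = id, field_id = as.character(field_id),
               area = nrow(mask_idx) * pixel_size^2,
               mean_gh2ax = max(mean(vals) - bg, 0),
               foci_count = .count_foci(sm, mask_idx, foci_min_prominence),
               cx_px = mean(mask_idx[, 1]), cy_px = mean(mask_idx[, 2]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify nuclei as gammaH2AX-damaged
#'
#' A nucleus is damaged when it has at least `min_foci` foci OR its
#' background-corrected mean gammaH2AX intensity exceeds the robust centre
#' of the undamaged population by `intensity_z` robust SDs (median + z * MAD
#' of nuclei below the foci criterion). Both thresholds are echoed in the
#' output attributes.
#'
#' @param records data.frame from [measure_nuclei()] (may span many fields;
#'   the intensity reference population is pooled over all rows).
#' @param min_foci Foci-count threshold.
#' @param intensity_z Robust-SD multiplier for the intensity criterion.
#' @return `records` with a logical `damaged` column; attribute `rule` holds
#'   the parameters and the derived intensity cutoff.
#' @export
classify_damaged <- function(records, min_foci = 3L, intensity_z = 3) {
  if (nrow(records) == 0L) {
    records$damaged <- logical(0)
    return(records)
  }
  by_foci <- records$foci_count >= min_foci
  ref <- records$mean_gh2ax[!by_foci]
  cutoff <- if (length(ref) >= 2L && stats::mad(ref) > 0) {
    # spread of the undamaged population; a zero MAD leaves the intensity
    # criterion undefined, so only the foci rule applies
    stats::median(ref) + intensity_z * stats::mad(ref)
  } else Inf
  records$damaged <- by_foci | (records$mean_gh2ax >= cutoff & cutoff > 0)
  attr(records, "rule") <- list(min_foci = min_foci, intensity_z = intensity_z,
                                intensity_cutoff = cutoff)
  records
}

#' Summarise damage per field
#'
#' @param records data.frame with `field_id` and `damaged` columns (from
#'   [classify_damaged()]); optionally `condition`.
#' @return data.frame (FieldSummary rows): `field_id`, `n_nuclei`,
#'   `pct_damaged` (0-100), and `condition` when present. Fields, not cells,
#'   are the replication unit for downstream statistics.
#' @export
summarize_fields <- function(records) {
  if (is.null(records$damaged))
    nm_stop("records must carry a 'damaged' column; run classify_damaged first",
            "invalid_input")
  if (nrow(records) == 0L)
    return(data.frame(field_id = character(), n_nuclei = integer(),
                      pct_damaged = numeric(), stringsAsFactors = FALSE))
  fields <- unique(records$field_id)
  out <- do.call(rbind, lapply(fields, function(fid) {
    d <- records[records$field_id == fid, ]
    r <- data.frame(field_id = fid, n_nuclei = nrow(d),
                    pct_damaged = 100 * mean(d$damaged),
                    stringsAsFactors = FALSE)
    if (!is.null(d$condition)) r$condition <- d$condition[1]
    r
  }))
  out
}

#' Score synthetic or real HCS fields end to end
#'
#' Segments every field's Hoechst channel, measures the gammaH2AX channel,
#' classifies damage (pooling the intensity reference across fields) and
#' summarises per field.
#'
#' @param fields List of per-field lists with `hoechst` and `gh2ax` matrices
#'   (e.g. `simulate_hcs_fields(cfg)$fields`).
#' @param pixel_size Pixel size (um/px).
#' @param min_foci,intensity_z Passed to [classify_damaged()].
#' @param ... Passed to [segment_nuclei()].
#' @return List with `records` (per-nucleus), `fields` (per-field summary).
#' @export
hcs_score_fields <- function(fields, pixel_size, min_foci = 3L,
                             intensity_z = 3, ...) {
  recs <- lapply(seq_along(fields), function(f) {
    lab <- segment_nuclei(fields[[f]]$hoechst, pixel_size, ...)
    measure_nuclei(lab, fields[[f]]$gh2ax, pixel_size,
                   field_id = sprintf("field_%02d", f))
  })
  records <- classify_damaged(do.call(rbind, recs), min_foci, intensity_z)
  list(records = records, fields = summarize_fields(records))
}
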