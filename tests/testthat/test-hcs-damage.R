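test_that("segmentation finds every non-overlapping nucleus and nothing in blanks", {
  cfg <- hcs_sim_config(damaged_fraction_true = 0.2, n_nuclei_per_field = 40,
                        n_fields = 1, seed = 41)
  sim <- simulate_hcs_fields(cfg)
  lab <- segment_nuclei(sim$fields[[1]]$hoechst, cfg$pixel_size)
  expect_equal(max(lab), 40)

  blank <- matrix(0.05, 200, 200)
  expect_equal(max(segment_nuclei(blank, cfg$pixel_size)), 0)
})

test_that("two touching ellipses are split by the watershed", {
  px <- 0.454
  img <- matrix(0.05, 140, 140)
  # two circles of radius 15 px touching at one tangent point
  for (c0 in list(c(55, 70), c(85, 70))) {
    xs <- rep(1:140, 140); ys <- rep(1:140, each = 140)
    inside <- (xs - c0[1])^2 + (ys - c0[2])^2 <= 15^2
    img[cbind(xs[inside], ys[inside])] <- 0.8
  }
  lab <- segment_nuclei(img, px, watershed_tolerance = 1)
  expect_equal(max(lab), 2)
})

test_that("measured areas follow pi*a*b and scale with pixel size", {
  # one ellipse with semi-axes 12.05 x 12.05 um -> area ~ 456 um^2
  px <- 0.227
  n <- 520
  img <- matrix(0.05, n, n)
  a_px <- 12.05 / px
  xs <- rep(1:n, n); ys <- rep(1:n, each = n)
  inside <- (xs - n / 2)^2 + (ys - n / 2)^2 <= a_px^2
  img[cbind(xs[inside], ys[inside])] <- 0.8
  lab <- segment_nuclei(img, px, max_area = 5000)
  expect_equal(max(lab), 1)
  rec <- measure_nuclei(lab, matrix(0, n, n), px)
  expect_equal(rec$area, pi * 12.05^2, tolerance = 0.02)
  expect_equal(rec$mean_gh2ax, 0)
  expect_equal(rec$foci_count, 0)

  # doubling pixel_size quadruples the reported area exactly
  rec2 <- measure_nuclei(lab, matrix(0, n, n), 2 * px)
  expect_equal(rec2$area, 4 * rec$area)
})

test_that("planted foci are counted and drive the damage call", {
  px <- 0.454
  n <- 160
  hoechst <- matrix(0.05, n, n)
  xs <- rep(1:n, n); ys <- rep(1:n, each = n)
  inside <- (xs - 80)^2 + (ys - 80)^2 <= 40^2
  hoechst[cbind(xs[inside], ys[inside])] <- 0.8
  gh2ax <- matrix(0.02, n, n)
  # 8 well-separated foci on a ring inside the nucleus
  ang <- 2 * pi * (0:7) / 8
  for (k in 1:8) {
    fx <- 80 + 22 * cos(ang[k]); fy <- 80 + 22 * sin(ang[k])
    wx <- floor(fx - 5):ceiling(fx + 5); wy <- floor(fy - 5):ceiling(fy + 5)
    gh2ax[wx, wy] <- gh2ax[wx, wy] +
      0.8 * outer(exp(-((wx - fx)^2) / (2 * 1.5^2)),
                  exp(-((wy - fy)^2) / (2 * 1.5^2)))
  }
  lab <- segment_nuclei(hoechst, px)
  rec <- measure_nuclei(lab, gh2ax, px)
  expect_gte(rec$foci_count, 7)
  expect_lte(rec$foci_count, 9)

  # classification rules
  recs <- data.frame(nucleus_id = 1:4, field_id = "f",
                     area = 180, mean_gh2ax = c(0.01, 0.012, 0.011, 0.011),
                     foci_count = c(0, 10, 2, 0))
  cls <- classify_damaged(recs, min_foci = 3)
  expect_equal(cls$damaged, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("field summaries count damaged nuclei per field", {
  recs <- data.frame(nucleus_id = 1:20, field_id = "f1", area = 180,
                     mean_gh2ax = 0.01, foci_count = 0,
                     damaged = c(rep(TRUE, 5), rep(FALSE, 15)))
  s <- summarize_fields(recs)
  expect_equal(s$pct_damaged, 25)
  expect_equal(s$n_nuclei, 20)

  # counting conservation across fields
  cfg <- hcs_sim_config(damaged_fraction_true = 0.2, n_nuclei_per_field = 30,
                        n_fields = 3, seed = 13)
  sim <- simulate_hcs_fields(cfg)
  res <- hcs_score_fields(sim$fields, cfg$pixel_size)
  expect_equal(sum(res$fields$n_nuclei), nrow(res$records))
  expect_equal(sum(res$records$damaged) + sum(!res$records$damaged),
               nrow(res$records))

  expect_error(summarize_fields(data.frame(field_id = "a")),
               class = "invalid_input")
})

test_that("generator plants exactly round(fraction * n) damaged nuclei (round-half-even)", {
  cfg <- hcs_sim_config(damaged_fraction_true = 0.374, n_nuclei_per_field = 100,
                        n_fields = 2, seed = 19)
  sim <- simulate_hcs_fields(cfg)
  per_field <- tapply(sim$truth$damaged, sim$truth$field_id, sum)
  expect_true(all(per_field == 37))

  # no damage -> no foci anywhere
  cfg0 <- hcs_sim_config(damaged_fraction_true = 0, n_nuclei_per_field = 20,
                         n_fields = 1, seed = 3)
  sim0 <- simulate_hcs_fields(cfg0)
  expect_true(all(sim0$truth$foci == 0))
  expect_true(all(!sim0$truth$damaged))

  # ellipse area ground truth: semi-axes 12.05 x 12.05 um -> ~456 um^2
  expect_equal(pi * 12.05 * 12.05, 456.2, tolerance = 1e-3)

  expect_error(hcs_sim_config(damaged_fraction_true = 1.5),
               class = "invalid_config")
})

test_that("segmentation matches generator instances one-to-one at default density", {
  cfg <- hcs_sim_config(damaged_fraction_true = 0.1, n_nuclei_per_field = 60,
                        n_fields = 1, seed = 77)
  sim <- simulate_hcs_fields(cfg)
  lab <- segment_nuclei(sim$fields[[1]]$hoechst, cfg$pixel_size)
  rec <- measure_nuclei(lab, sim$fields[[1]]$gh2ax, cfg$pixel_size)
  tru <- sim$truth
  # match by centroid distance; require >= 98% matched with area agreement
  matched <- 0
  for (i in seq_len(nrow(rec))) {
    d <- sqrt((tru$cx_px - rec$cx_px[i])^2 + (tru$cy_px - rec$cy_px[i])^2)
    j <- which.min(d)
    if (d[j] < 5 && abs(rec$area[i] - tru$area_um2[j]) / tru$area_um2[j] < 0.15)
      matched <- matched + 1
  }
  expect_gte(matched / nrow(tru), 0.98)
  expect_equal(nrow(rec), nrow(tru))
})

test_that("recovered damaged percentage tracks the truth across fractions", {
  for (frac in c(0.05, 0.60)) {
    cfg <- hcs_sim_config(damaged_fraction_true = frac,
                          n_nuclei_per_field = 60, n_fields = 4,
                          seed = round(1000 * frac) + 7)
    sim <- simulate_hcs_fields(cfg)
    res <- hcs_score_fields(sim$fields, cfg$pixel_size)
    expect_lt(abs(mean(res$fields$pct_damaged) - 100 * mean(sim$truth$damaged)),
              2)
  }
})
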