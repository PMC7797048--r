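# Shared recovery-study drivers: simulate at a known ground truth and run
# the corresponding analysis pipeline, mirroring the designs of the study
# being emulated.

recover_afm_grand_mean <- function(E_true_pa, n_cells, curves_per_cell = 10,
                                   noise_sd = 1, seed = 1) {
  cell_means <- vapply(seq_len(n_cells), function(ci) {
    fits <- lapply(seq_len(curves_per_cell), function(pt) {
      cfg <- afm_sim_config(E_true = E_true_pa, k = 30, nu = 0.5,
                            theta = 17.5 * pi / 180, noise_sd = noise_sd,
                            z0 = 2000, seed = seed + 1000L * ci + pt)
      analyze_force_curve(simulate_force_curve(cfg))
    })
    aggregate_cell(fits, sprintf("cell_%02d", ci))$E_mean
  }, numeric(1))
  mean(cell_means)
}

recover_spt_mean_D <- function(D_true, n_tracks = 200, alpha = 1,
                               dt = 0.032, duration_s = 30, loc_sd = 20,
                               seed = 1) {
  cfg <- spt_sim_config(D_true = D_true, alpha = alpha, dt = dt,
                        n_frames = round(duration_s / dt),
                        n_particles = n_tracks, loc_sd = loc_sd, seed = seed)
  tracks <- simulate_fbm_tracks(cfg)
  # the study's track filters: <= 400 nm frame steps would gate a tracker;
  # simulated tracks are complete, so only the 10-frame minimum applies
  tracks <- Filter(function(t) nrow(t$points) >= 10, tracks)
  fits <- fit_tracks_msd(tracks, dt = dt)
  summarize_diffusion(fits, "recovery")
}

recover_hcs_pct <- function(fraction, n_fields = 20, n_per_field = 100,
                            seed = 1) {
  cfg <- hcs_sim_config(damaged_fraction_true = fraction,
                        n_nuclei_per_field = n_per_field,
                        n_fields = n_fields, seed = seed)
  sim <- simulate_hcs_fields(cfg)
  res <- hcs_score_fields(sim$fields, cfg$pixel_size)
  list(mean_pct = mean(res$fields$pct_damaged),
       truth_pct = 100 * mean(sim$truth$damaged))
}

recover_hcs_area <- function(area_mean = 456, area_sd = 10.8 * sqrt(139),
                             n_total = 139, pixel_size = 0.227, seed = 1) {
  per_field <- 14L
  n_fields <- ceiling(n_total / per_field)
  counts <- rep(per_field, n_fields)
  counts[n_fields] <- n_total - per_field * (n_fields - 1)
  cfg <- hcs_sim_config(damaged_fraction_true = 0,
                        n_nuclei_per_field = counts, n_fields = n_fields,
                        nucleus_area_mean = area_mean, nucleus_area_sd = area_sd,
                        pixel_size = pixel_size, seed = seed)
  sim <- simulate_hcs_fields(cfg)
  areas <- unlist(lapply(seq_along(sim$fields), function(f) {
    lab <- segment_nuclei(sim$fields[[f]]$hoechst, pixel_size, max_area = 5000)
    measure_nuclei(lab, sim$fields[[f]]$gh2ax, pixel_size)$area
  }))
  list(mean_area = mean(areas), truth_mean = mean(sim$truth$area_um2),
       n = length(areas))
}
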