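make_flat_series <- function(R, n = 5) {
  tibble::tibble(time_s = (seq_len(n) - 1) / 30, R_um = rep(R, n))
}

test_that("noiseless render + default extraction is the identity on R", {
  cfg <- imaging_config(noise = FALSE, seed = 3)
  for (R in c(2, 3, 4)) {
    st <- render_stack(make_flat_series(R), cfg)
    ex <- extract_series(st)
    # within 2 px (0.2 um at 0.1 um/px)
    expect_equal(mean(ex$R_um), R, tolerance = 0.2 / R)
  }
})

test_that("expected photon count is conserved as the blob elongates", {
  cfg <- imaging_config(noise = FALSE, background_photons = 0,
                        fluctuate_orientation = FALSE)
  totals <- vapply(c(2, 3, 4), function(R) {
    st <- render_stack(make_flat_series(R, n = 1), cfg)
    sum(st$frames[[1]])
  }, numeric(1))
  expect_equal(totals / totals[2], rep(1, 3), tolerance = 0.01)
})

test_that("blob exceeding the frame raises an error naming the frame", {
  s <- tibble::tibble(time_s = c(0, 1 / 30), R_um = c(3, 40))
  expect_error(render_stack(s, imaging_config()), "frame 2")
})

test_that("zero signal yields no detection and a hard error on a blank stack", {
  cfg <- imaging_config(peak_photons = 0, seed = 6)
  st <- render_stack(make_flat_series(3, n = 10), cfg)
  expect_error(extract_series(st), "unusable stack")
})

test_that("TIFF + sidecar round trip is bit-exact and carries calibration", {
  p <- control_params()
  s <- simulate_gp(p, sampling_spec(n_frames = 10, n_molecules = 1, seed = 12))
  st <- render_stack(s, imaging_config(seed = 13))
  path <- file.path(withr::local_tempdir(), "stack.tif")
  write_stack(st, path, ground_truth = list(k = p$k))
  rd <- read_stack(path)
  expect_identical(rd$frames, st$frames)
  expect_equal(rd$pixel_size_um, st$pixel_size_um)
  expect_equal(rd$frame_interval_s, st$frame_interval_s)
  expect_equal(rd$meta$ground_truth$k, p$k)
  # missing sidecar refused
  file.remove(paste0(path, ".json"))
  expect_error(read_stack(path), "sidecar")
})

test_that("extraction is invariant to 90-degree rotation and intensity scale", {
  p <- control_params()
  s <- simulate_gp(p, sampling_spec(n_frames = 40, n_molecules = 1, seed = 14))
  st <- render_stack(s, imaging_config(seed = 15))
  ex <- extract_series(st)
  rot <- st
  rot$frames <- lapply(st$frames, function(m) t(m)[ncol(m):1, , drop = FALSE])
  ex_rot <- extract_series(rot)
  expect_equal(ex_rot$R_um, ex$R_um, tolerance = 0.1 / min(ex$R_um))
  scl <- st
  scl$frames <- lapply(st$frames, function(m) m * 0.5)
  ex_scl <- extract_series(scl)
  expect_equal(ex_scl$R_um, ex$R_um)
})

test_that("extracted length grows strictly with the rendered major axis", {
  cfg <- imaging_config(noise = FALSE, fluctuate_orientation = FALSE)
  Rs <- seq(2, 4, by = 0.5)
  got <- vapply(Rs, function(R) {
    mean(extract_series(render_stack(make_flat_series(R, 2), cfg))$R_um)
  }, numeric(1))
  expect_true(all(diff(got) > 0))
})

test_that("alternative background and long-axis settings stay close to truth", {
  cfg <- imaging_config(noise = FALSE, fluctuate_orientation = FALSE)
  st <- render_stack(make_flat_series(3, 4), cfg)
  rb <- extract_series(st, extraction_config(background_method = "rolling-ball"))
  expect_equal(mean(rb$R_um), 3, tolerance = 0.1)
  qt <- extract_series(st, extraction_config(threshold_method = "fixed-quantile",
                                             quantile = 0.985))
  expect_gt(mean(qt$R_um), 1.5)
  pa <- extract_series(st, extraction_config(long_axis_definition = "principal-axis"))
  # moment-based definition measures ~2 sigma_major, not the full extent
  expect_true(all(pa$R_um > 0.5 & pa$R_um < 3))
})

test_that("a noisy rendered recording still yields the ground-truth stiffness", {
  p <- control_params()
  s <- simulate_gp(p, sampling_spec(n_frames = 3000, n_molecules = 1, seed = 9))
  st <- render_stack(s, imaging_config(seed = 10))
  ex <- extract_series(st, molecule_id = "mol01")
  expect_lt(attr(ex, "n_excluded"), 0.02 * 3000)
  f <- fit_molecules(ex[, c("molecule_id", "time_s", "R_um")], gaps = "pairwise")
  expect_equal(f$k_N_per_m, p$k, tolerance = 0.15)
  # the extracted series' ACF tracks the generator ground truth at lags 1-10
  ac <- autocovariance(ex[, c("molecule_id", "time_s", "R_um")],
                       max_lag_s = 1, gaps = "pairwise")
  th <- theoretical_acf(p, ac$lag_s)
  se <- th$C_um2[1] * sqrt(2 / (p$gamma * 100))
  expect_lt(max(abs(ac$C_um2[2:11] - th$C_um2[2:11])), 4 * se)
})

test_that("median-frame background suits a wandering blob, not a pinned one", {
  # a pinned, frozen-orientation blob is its own median: nothing survives
  cfg <- imaging_config(noise = FALSE, fluctuate_orientation = FALSE)
  st <- render_stack(make_flat_series(3, 10), cfg)
  expect_error(
    extract_series(st, extraction_config(background_method = "median-frame")),
    "unusable stack"
  )
})
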