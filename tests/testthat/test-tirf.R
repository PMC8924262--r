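# Spot detection, linking, MSD and motility classification.

test_that("DoG detection finds bright spots with sub-pixel accuracy", {
  cfg <- tirf_config(n_frames = 2, frame_shape = c(48, 48), noise_sd = 5)

  # blank frames: no detections in at least 95% of seeded frames
  blanks <- purrr::map_int(1:40, function(i) {
    mv <- simulate_tirf_movie(cfg, list(), seed = i)
    nrow(detect_spots(mv$frames[, , 1], quality_min = 10))
  })
  expect_gte(mean(blanks == 0), 0.95)

  # one bright spot: found within half a pixel
  mv1 <- simulate_tirf_movie(
    cfg, list(list(model = motion_model("diffusion", d_um2_s = 0),
                   x0_um = 2.17, y0_um = 3.02)), seed = 3)
  sp <- detect_spots(mv1$frames[, , 1])
  expect_equal(nrow(sp), 1)
  expect_lt(sqrt((sp$x_um - 2.17)^2 + (sp$y_um - 3.02)^2), 0.5 * 0.11)

  # two spots separated by 5 PSF sigma resolve
  sep <- 5 * cfg$psf_sigma_um
  mv2 <- simulate_tirf_movie(
    cfg, list(list(model = motion_model("diffusion", d_um2_s = 0),
                   x0_um = 2, y0_um = 2),
              list(model = motion_model("diffusion", d_um2_s = 0),
                   x0_um = 2 + sep, y0_um = 2)), seed = 4)
  expect_equal(nrow(detect_spots(mv2$frames[, , 1])), 2)

  expect_error(detect_spots(matrix(0, 10, 10), pixel_size_um = 0.5),
               "2 pixels")
})

test_that("linking builds tracks, closes small gaps and enforces duration", {
  still <- tibble::tibble(frame = rep(1:50, each = 1),
                          x_um = 2, y_um = 3)
  trk <- link_tracks(still, min_duration = 40)
  expect_equal(length(unique(trk$track_id)), 1)
  expect_equal(nrow(trk), 50)

  # a 3-frame hole exceeds max_gap = 2: the track is split and, with the
  # 40-frame filter relaxed, both halves survive
  holey <- still[!(still$frame %in% 20:22), ]
  trk2 <- link_tracks(holey, max_gap = 2, min_duration = 5)
  expect_equal(length(unique(trk2$track_id)), 2)
  # a 2-frame hole is closed and interpolated
  holey2 <- still[!(still$frame %in% 20:21), ]
  trk3 <- link_tracks(holey2, max_gap = 2, min_duration = 5)
  expect_equal(length(unique(trk3$track_id)), 1)
  expect_equal(sum(trk3$interpolated), 2)

  # duration filter: nothing under 40 frames is emitted
  expect_equal(nrow(link_tracks(holey, max_gap = 2, min_duration = 40)), 0)

  expect_equal(nrow(link_tracks(still[0, ])), 0)
})

test_that("linking recovers ground-truth associations at low density", {
  cfg <- tirf_config(n_frames = 50, frame_shape = c(64, 64), noise_sd = 5)
  # spots on a jittered grid: mean step (~0.09 um) well under the 0.5 um link
  # distance, spots well separated so identities are unambiguous
  withr::with_seed(11, {
    grid <- expand.grid(x = c(1.2, 3.3, 5.4), y = c(1.2, 3.3, 5.4))
    motions <- purrr::pmap(grid, function(x, y) {
      list(model = motion_model("diffusion", d_um2_s = 0.02),
           x0_um = x + runif(1, -0.2, 0.2), y0_um = y + runif(1, -0.2, 0.2))
    })
  })
  mv <- simulate_tirf_movie(cfg, motions, seed = 12)
  sp <- detect_spots_movie(mv)
  trk <- link_tracks(sp, min_duration = 40)
  # each emitted link should connect detections of the same ground-truth spot
  matched <- dplyr::inner_join(
    trk, mv$truth, by = "frame", suffix = c("", "_true"),
    relationship = "many-to-many") |>
    dplyr::mutate(d = sqrt((x_um - x_um_true)^2 + (y_um - y_um_true)^2)) |>
    dplyr::group_by(track_id, frame) |>
    dplyr::slice_min(d, n = 1, with_ties = FALSE) |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(purity = max(table(track_id_true)) / dplyr::n())
  expect_gte(min(matched$purity), 0.95)
})

test_that("MSD estimator honours closed forms and time-reversal symmetry", {
  still <- tibble::tibble(frame = 1:50, x_um = 1, y_um = 1)
  expect_true(all(compute_msd(still)$msd_um2 == 0))

  # deterministic drift: msd(tau) = v^2 tau^2 exactly
  v <- 0.8; dt <- 0.1
  drift <- tibble::tibble(frame = 1:60, x_um = v * dt * (0:59), y_um = 0)
  m <- compute_msd(drift, frame_rate_hz = 10)
  expect_equal(m$msd_um2, v^2 * m$lag_s^2, tolerance = 1e-12)

  # time reversal leaves the estimator unchanged
  withr::with_seed(5, {
    tr <- simulate_trajectory(motion_model("diffusion", d_um2_s = 0.05),
                              n_frames = 80, dt_s = 0.1)
  })
  rev_tr <- tibble::tibble(frame = tr$frame, x_um = rev(tr$x_um),
                           y_um = rev(tr$y_um))
  expect_equal(compute_msd(tr)$msd_um2, compute_msd(rev_tr)$msd_um2,
               tolerance = 1e-12)

  expect_error(compute_msd(still[1:3, ]), "at least 4")
  expect_s3_class(autoplot(m), "ggplot")
})

test_that("track classification separates the four motion regimes", {
  # pure drift: alpha = 2 -> directed
  drift <- tibble::tibble(frame = 1:60, x_um = 0.05 * (0:59), y_um = 0)
  cl <- classify_track(compute_msd(drift, 10), drift)
  expect_equal(cl$category, "directed")

  # degenerate all-zero MSD -> confined, flagged
  still <- tibble::tibble(frame = 1:50, x_um = 1, y_um = 1)
  cl0 <- classify_track(compute_msd(still, 10), still)
  expect_equal(cl0$category, "confined")
  expect_true(cl0$flagged)

  # seeded panels: ground-truth Brownian and confined tracks classify
  # correctly in at least 85% of cases
  withr::with_seed(31, {
    brown <- purrr::map_chr(1:60, function(i) {
      tr <- simulate_trajectory(motion_model("diffusion", d_um2_s = 0.05),
                                n_frames = 100, dt_s = 0.1)
      classify_track(compute_msd(tr, 10), tr)$category
    })
    conf <- purrr::map_chr(1:60, function(i) {
      tr <- simulate_trajectory(
        motion_model("confined", d_um2_s = 0.2, corral_radius_um = 0.15),
        n_frames = 100, dt_s = 0.1)
      classify_track(compute_msd(tr, 10), tr)$category
    })
  })
  expect_gte(mean(brown == "normal diffusion"), 0.85)
  expect_gte(mean(conf == "confined"), 0.85)
})

test_that("cluster diameter implements the 2-sigma rule", {
  cfg <- tirf_config(n_frames = 2, frame_shape = c(32, 32),
                     psf_sigma_um = 2 * 0.11, noise_sd = 0)
  mv <- simulate_tirf_movie(
    cfg, list(list(model = motion_model("diffusion", d_um2_s = 0),
                   x0_um = 1.65, y0_um = 1.65)), seed = 1)
  fit <- cluster_diameter(mv$frames[, , 1])
  expect_true(fit$converged)
  # sigma = 2 px = 0.22 um -> diameter 0.44 um
  expect_equal(fit$diameter_um, 0.44, tolerance = 0.02 * 0.44)
  expect_equal(fit$sigma_x_um, cfg$psf_sigma_um, tolerance = 1e-4)
  expect_equal(fit$sigma_y_um, cfg$psf_sigma_um, tolerance = 1e-4)

  # noisy spots (SNR ~ 10): median diameter within 10% of 2 sigma
  cfgn <- tirf_config(n_frames = 2, frame_shape = c(32, 32),
                      psf_sigma_um = 0.15, spot_amplitude = 400,
                      noise_sd = 40)
  ds <- purrr::map_dbl(1:30, function(i) {
    mvn <- simulate_tirf_movie(
      cfgn, list(list(model = motion_model("diffusion", d_um2_s = 0),
                      x0_um = 1.65, y0_um = 1.65)), seed = 100 + i)
    cluster_diameter(mvn$frames[8:24, 8:24, 1])$diameter_um
  })
  expect_lt(abs(median(ds) - 0.3) / 0.3, 0.1)
})

test_that("cluster density is count over area", {
  expect_equal(cluster_density(50, 100), 0.5)
  expect_equal(cluster_density(tibble::tibble(x_um = numeric()), 10), 0)
  expect_error(cluster_density(5, 0), "area")

  # planted spots on a blank background: density is exact at full recall
  cfg <- tirf_config(n_frames = 2, frame_shape = c(64, 64), noise_sd = 3)
  withr::with_seed(8, {
    pos <- expand.grid(x = seq(1, 6, length.out = 3),
                       y = seq(1, 6, length.out = 3))
    motions <- purrr::pmap(pos, function(x, y) {
      list(model = motion_model("diffusion", d_um2_s = 0), x0_um = x, y0_um = y)
    })
  })
  mv <- simulate_tirf_movie(cfg, motions, seed = 9)
  sp <- detect_spots(mv$frames[, , 1])
  area <- (64 * 0.11)^2
  expect_equal(cluster_density(sp, area), 9 / area)
})

test_that("detection and linking are invariant to integer pixel shifts", {
  cfg <- tirf_config(n_frames = 45, frame_shape = c(48, 48), noise_sd = 5)
  withr::with_seed(14, {
    motions <- purrr::map(1:3, function(i) {
      list(model = motion_model("diffusion", d_um2_s = 0.01),
           x0_um = runif(1, 2.2, 3), y0_um = runif(1, 2.2, 3))
    })
  })
  mv <- simulate_tirf_movie(cfg, motions, seed = 15)
  shift_px <- 4L
  shifted <- array(cfg$background, dim = dim(mv$frames))
  shifted[, (1 + shift_px):48, ] <- mv$frames[, 1:(48 - shift_px), ]

  t1 <- link_tracks(detect_spots_movie(mv$frames, 0.11), min_duration = 40)
  t2 <- link_tracks(detect_spots_movie(shifted, 0.11), min_duration = 40)
  expect_equal(nrow(t1), nrow(t2))
  expect_equal(t2$x_um, t1$x_um + shift_px * 0.11, tolerance = 1e-6)
  expect_equal(t2$y_um, t1$y_um, tolerance = 1e-6)
})
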