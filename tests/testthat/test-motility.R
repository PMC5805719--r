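test_that("down-sampling keeps every k-th frame from frame zero", {
  tr <- straight_track(v = 1, frame_rate = 10, n_frames = 11)
  ds <- downsample_track(tr, 2)
  expect_equal(length(ds$x), 3)            # frames {0, 5, 10}
  expect_equal(ds$x, tr$x[c(1, 6, 11)])
  expect_equal(ds$frame_rate, 2)
  # identity at equal rates; error on non-integer ratio
  expect_equal(downsample_track(ds, 2)$x, ds$x)
  expect_error(downsample_track(tr, 3), "integer multiple")
})

test_that("track velocity is mean step length over frame interval", {
  uni <- filament_track("u", x = c(0, 1, 2), y = c(0, 0, 0), frame_rate = 2)
  expect_equal(track_velocity(uni), 2)
  still <- filament_track("s", x = c(1, 1, 1), y = c(2, 2, 2),
                          frame_rate = 2)
  expect_equal(track_velocity(still), 0)
  zig <- filament_track("z", x = c(0, 1, 1), y = c(0, 0, 1), frame_rate = 1)
  expect_equal(track_velocity(zig), 1)
})

test_that("down-sampling a noiseless straight track preserves velocity", {
  tr <- straight_track(v = 3.2, frame_rate = 10, n_frames = 41)
  expect_equal(track_velocity(downsample_track(tr, 2)),
               track_velocity(tr), tolerance = 1e-12)
})

test_that("mobility classification is inclusive at the velocity threshold", {
  still <- filament_track("s", x = rep(0, 5), y = rep(0, 5), frame_rate = 2)
  expect_false(classify_mobile(still))
  fast <- straight_track(v = 4, frame_rate = 2, n_frames = 9)
  expect_true(classify_mobile(fast))
  exact <- straight_track(v = 0.3, frame_rate = 2, n_frames = 9)
  expect_true(classify_mobile(exact, v_min = 0.3))
})

test_that("motility statistic combines fraction and velocity", {
  tracks <- list(straight_track(2, 2, 9, "a"), straight_track(4, 2, 9, "b"),
                 filament_track("c", rep(0, 9), rep(0, 9), frame_rate = 2),
                 filament_track("d", rep(1, 9), rep(1, 9), frame_rate = 2))
  st <- motility_statistic(tracks)
  expect_equal(st$fraction_moving, 0.5)
  expect_equal(st$mean_velocity, 3)
  expect_equal(st$product, 1.5)
  expect_equal(st$n_filaments, 4)
  # all immobile -> product 0; all mobile at 5 um/s -> product 5
  st0 <- motility_statistic(tracks[3:4])
  expect_equal(st0$product, 0)
  st5 <- motility_statistic(list(straight_track(5, 2, 9, "a"),
                                 straight_track(5, 2, 9, "b")))
  expect_equal(st5$product, 5)
  expect_error(motility_statistic(list()), "no tracks")
})

test_that("product never exceeds the fastest filament", {
  set.seed(21)
  for (i in 1:20) {
    tracks <- lapply(1:10, function(k)
      straight_track(runif(1, 0, 6), 2, 9, paste0("f", k)))
    st <- motility_statistic(tracks)
    vmax <- max(vapply(tracks, track_velocity, numeric(1)))
    expect_lte(st$product, vmax + 1e-12)
  }
})

test_that("per-movie SEM is used when movie labels are present", {
  tracks <- c(lapply(1:4, function(k)
                straight_track(2 + k / 10, 2, 9, paste0("a", k), "m1")),
              lapply(1:4, function(k)
                straight_track(3 + k / 10, 2, 9, paste0("b", k), "m2")),
              lapply(1:4, function(k)
                straight_track(4 + k / 10, 2, 9, paste0("c", k), "m3")))
  st <- motility_statistic(tracks)
  per_movie <- c(mean(2.1 + 0:3 / 10), mean(3.1 + 0:3 / 10),
                 mean(4.1 + 0:3 / 10))
  expect_equal(st$sem, sd(per_movie) / sqrt(3), tolerance = 1e-9)
})

test_that("noiseless sigmoidal dose-response is recovered exactly", {
  grid <- seq(4.5, 8.5, by = 0.5)
  prod <- 4 / (1 + 10^(1.5 * (grid - 6.5)))
  fit <- dose_response(data.frame(pca = grid, product = prod))
  expect_equal(fit$pca50, 6.5, tolerance = 1e-6)
  expect_equal(fit$n_h, 1.5, tolerance = 1e-6)
  expect_error(dose_response(data.frame(pca = grid,
                                        product = rep(0, length(grid)))),
               "degenerate")
})

test_that("a leftward pCa50 shift is recovered from noisy dose-responses", {
  set.seed(11)
  grid <- seq(4.5, 8.5, by = 0.5)
  truth <- c(control = 6.5, treated = 6.9)
  deltas <- vapply(1:100, function(i) {
    y0 <- 4 / (1 + 10^(2 * (grid - truth["control"]))) + rnorm(9, 0, 0.1)
    y1 <- 4 / (1 + 10^(2 * (grid - truth["treated"]))) + rnorm(9, 0, 0.1)
    dose_response(data.frame(pca = grid, product = y1))$pca50 -
      dose_response(data.frame(pca = grid, product = y0))$pca50
  }, numeric(1))
  expect_lt(abs(mean(deltas) - 0.4),
            2 * sd(deltas) / sqrt(length(deltas)) + 0.02)
})

test_that("generated tracks reproduce the encoded mobility extremes", {
  cond <- data.frame(pca = c(9, 4), isoform = "none", frag_conc = 0)
  df <- gen_tracks(cond, n_filaments = 200, seed = 5)
  truth <- attr(df, "ground_truth")
  lo <- analyze_tracks(df[df$pca == 9, ])
  hi <- analyze_tracks(df[df$pca == 4, ])
  se <- sqrt(truth$p_max * (1 - truth$p_max) / 200)
  expect_lt(lo$fraction_moving, truth$p_base + 3 * se + 0.02)
  expect_lt(abs(hi$fraction_moving - truth$p_max), 3 * se + 0.02)
  # recovered velocity of mobile filaments near the encoded speed
  expect_lt(abs(hi$mean_velocity - truth$v0) / truth$v0, 0.05)
})

test_that("pipeline recovers encoded fraction and velocity within 2 SEM", {
  cond <- data.frame(pca = 5.8, isoform = "none", frag_conc = 0)
  df <- gen_tracks(cond, n_filaments = 300, seed = 9)
  truth <- attr(df, "ground_truth")
  st <- analyze_tracks(df)
  L <- 1 / (1 + 10^(truth$n_mobile * (5.8 - truth$pca50_mobile)))
  p_true <- truth$p_base + (truth$p_max - truth$p_base) * L
  se_f <- sqrt(p_true * (1 - p_true) / 300)
  expect_lt(abs(st$fraction_moving - p_true), 2 * se_f + 0.01)
  se_v <- truth$speed_cv * truth$v0 / sqrt(300 * p_true)
  expect_lt(abs(st$mean_velocity - truth$v0), 2 * se_v + 0.05)
})

test_that("tracks round-trip through the CSV schema", {
  cond <- data.frame(pca = 4, isoform = "none", frag_conc = 0)
  df <- gen_tracks(cond, n_filaments = 5, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_tracks(df, path)
  back <- read_tracks(path)
  expect_equal(back$x_um, df$x_um, tolerance = 1e-9)
  st1 <- analyze_tracks(df)
  st2 <- analyze_tracks(back)
  expect_equal(st2$product, st1$product, tolerance = 1e-9)
})
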