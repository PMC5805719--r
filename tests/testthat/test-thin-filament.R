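p_gamma1 <- thin_filament_params(gamma = 1)

test_that("effective rates combine calcium and fragment pathways", {
  p <- thin_filament_params()
  none <- isoform_defaults("none")
  card <- isoform_defaults("cardiac")
  # no activator: a = 0
  r0 <- effective_rates(p, none, frag_conc = 0, ca = 0)
  expect_equal(r0$a, 0)
  expect_equal(r0$b, p$k_off)
  # saturating fragment, no calcium: a -> k_act
  rs <- effective_rates(p, card, frag_conc = 1, ca = 0)
  expect_equal(rs$a, card$k_act, tolerance = 1e-6)
  # half-occupancy algebra: frag = Kd and ca = ca50 -> a = k_on_max/2 + k_act/2
  rh <- effective_rates(p, card, frag_conc = card$kd_frag, ca = p$ca50_tn)
  expect_equal(rh$a, p$k_on_max / 2 + card$k_act / 2)
  expect_error(effective_rates(p, card, frag_conc = -1e-6, ca = 1e-6),
               ">= 0")
})

test_that("single-unit steady state solves the flux balance", {
  expect_equal(steady_state_single_unit(list(a = 0, b = 1, f = 1, g = 1)),
               c(pi_b = 1, pi_c = 0, pi_m = 0))
  expect_equal(steady_state_single_unit(list(a = 1, b = 1, f = 1, g = 1)),
               c(pi_b = 1, pi_c = 1, pi_m = 1) / 3)
  expect_equal(steady_state_single_unit(list(a = 10, b = 1, f = 5, g = 2)),
               c(pi_b = 1, pi_c = 10, pi_m = 25) / 36)
  # absorbing limits resolve rather than error
  expect_equal(steady_state_single_unit(list(a = 1, b = 1, f = 1, g = 0)),
               c(pi_b = 0, pi_c = 0, pi_m = 1))
  expect_equal(steady_state_single_unit(list(a = 1, b = 0, f = 0, g = 1)),
               c(pi_b = 0, pi_c = 1, pi_m = 0))
})

test_that("no pathway out of blocked leaves the chain silent", {
  tr <- simulate_chain(p_gamma1, ca = 0, duration = 0.5, seed = 3)
  expect_true(all(tr$y == 0))
})

test_that("identical seeds give bit-identical trajectories", {
  a <- simulate_chain(p_gamma1, ca = 1e-6, duration = 0.5, seed = 11)
  b <- simulate_chain(p_gamma1, ca = 1e-6, duration = 0.5, seed = 11)
  expect_identical(a$y, b$y)
  expect_identical(attr(a, "state"), attr(b, "state"))
  c2 <- simulate_chain(p_gamma1, ca = 1e-6, duration = 0.5, seed = 12)
  expect_false(identical(a$y, c2$y))
})

test_that("state fractions always sum to one", {
  tr <- simulate_chain(thin_filament_params(), ca = 3e-6, duration = 0.5,
                       seed = 5)
  tot <- attr(tr, "pi_b") + attr(tr, "pi_c") + tr$y
  expect_equal(tot, rep(1, length(tot)))
})

test_that("uncoupled chain time-average matches the analytic steady state", {
  ca <- 5e-6
  r <- effective_rates(p_gamma1, isoform_defaults("none"), 0, ca)
  ss <- steady_state_single_unit(r)
  reps <- vapply(1:6, function(s) {
    tr <- simulate_chain(p_gamma1, ca = ca, duration = 10, seed = s)
    mean(tr$y[tr$t > 5])
  }, numeric(1))
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - ss[["pi_m"]]), 3 * se + 0.01 * ss[["pi_m"]])
})

test_that("dt stability guard names the required time step", {
  expect_error(simulate_chain(p_gamma1, ca = 1e-3, duration = 1, dt = 0.01,
                              seed = 1),
               "need dt <=")
})

test_that("release zeroes bound crossbridges and recovery is stationary", {
  p <- thin_filament_params(n_units = 200, gamma = 1)
  tr <- simulate_ktr(p, ca = 1e-3, t_release = 1.5, duration = 4, seed = 4)
  expect_equal(tr$y[tr$t == 0], 0)
  pre <- mean(tr$y[tr$t < 0 & tr$t > -0.5])
  plateau <- mean(tr$y[tr$t > 2])
  expect_lt(abs(plateau - pre), 0.05)
})

test_that("calcium transient starts diastolic and peaks at the set level", {
  tg <- seq(0, 1, by = 1e-5)
  tr <- ca_transient(tg, pca_dia = 7, pca_peak = 5.8, tau_rise = 0.03,
                     tau_decay = 0.15)
  expect_equal(tr$y[1], 1e-7)
  expect_lte(max(tr$y), 10^-5.8 * (1 + 1e-12))
  expect_gte(max(tr$y), 10^-5.8 * (1 - 1e-6))
  # degenerate amplitude: flat trace
  flat <- ca_transient(tg, pca_dia = 7, pca_peak = 7)
  expect_true(all(flat$y == 1e-7))
  expect_error(ca_transient(tg, tau_rise = 0.2, tau_decay = 0.1),
               "tau_rise")
})

test_that("flat diastolic drive leaves sarcomere length at rest", {
  p <- thin_filament_params()
  tran <- ca_transient(seq(0, 0.5, by = 1e-3), pca_dia = 9, pca_peak = 9)
  tw <- simulate_twitch(p, transient = tran, sl_rest = 1.8, seed = 2,
                        lead_in = 0.1)
  expect_true(all(tw$y == 1.8))
})

test_that("rectangular activation pulse relaxes at the restoring rate", {
  p <- thin_filament_params()
  dt <- 1e-4
  n <- 10000L                     # 1 s
  pulse <- c(rep(0.5, 3000L), rep(0, n - 3000L))
  tw <- simulate_twitch(p, transient = new_trace(seq_len(n) * dt,
                                                 rep(1e-9, n), units = "M"),
                        sl_rest = 1.8, v_max = 4, k_restore = 12,
                        dt = dt, seed = 1, pi_m = pulse)
  # post-pulse recovery is the linear ODE's exponential with rate k_restore
  post <- tw$t > 0.31 & tw$t < 0.8
  d <- 1.8 - tw$y[post]
  fit <- stats::lm(log(d) ~ tw$t[post])
  expect_equal(-1 / stats::coef(fit)[[2]], 1 / 12, tolerance = 0.02)
})

test_that("force-pCa curve is near zero at pCa 9 and self-normalizes", {
  p <- thin_filament_params()
  fc <- force_pca_curve(p, pca_grid = c(4.5, 6, 9), duration = 4, seed = 2,
                        normalized = TRUE)
  expect_equal(fc$pi_m[fc$pca == 4.5], 1)
  expect_lt(fc$pi_m[fc$pca == 9], 0.02)
})

test_that("cardiac fragment shifts the fitted pCa50 leftward", {
  p <- thin_filament_params()
  grid <- c(4.5, 5.11, 5.42, 5.61, 5.77, 6.0, 6.5, 7.0, 10.0)
  shifts <- vapply(1:3, function(s) {
    f0 <- fit_hill(force_pca_curve(p, pca_grid = grid, duration = 6,
                                   seed = s)$pca,
                   force_pca_curve(p, pca_grid = grid, duration = 6,
                                   seed = s)$pi_m)
    fc <- force_pca_curve(p, isoform_defaults("cardiac"), 2e-8,
                          pca_grid = grid, duration = 6, seed = s)
    f1 <- fit_hill(fc$pca, fc$pi_m)
    f1$pca50 - f0$pca50
  }, numeric(1))
  expect_true(all(shifts > 0))
})

test_that("Hill coefficient of the simulated curve rises with coupling", {
  nh <- vapply(c(1, 40, 100), function(g) {
    p <- thin_filament_params(n_units = 12, k_on_max = 5, k_off = 10,
                              f_app = 5, g_app = 2, gamma = g,
                              ca50_tn = 5e-6)
    fc <- force_pca_curve(p, pca_grid = seq(4.5, 8.5, by = 0.5),
                          duration = 6, dt = "auto", seed = 7, n_reps = 3)
    fit_hill(fc$pca, fc$pi_m)$n_h
  }, numeric(1))
  expect_true(all(diff(nh) >= 0))
})
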