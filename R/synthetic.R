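#' Generate a synthetic force-pCa dataset with declared ground truth
#'
#' Samples a 4-parameter logistic in pCa plus i.i.d. Gaussian noise,
#' clipped at zero. The default grid is the standard activating-titration
#' series (pCa 4.50, 5.11, 5.42, 5.61, 5.77, 6.00 and the relaxed 10.00).
#'
#' @param pca50,n_h,floor,ceiling Generating curve parameters.
#' @param noise_sd Gaussian noise SD (relative-force units).
#' @param pca_grid pCa values sampled.
#' @param seed Integer seed (mandatory; no global random state is relied
#'   on).
#' @param fiber_id Fiber label stored in the dataset.
#' @return data.frame with columns `fiber_id`, `pca`, `force`; the
#'   generating parameters (including the seed) are attached as attribute
#'   `ground_truth`.
#' @export
gen_force_pca <- function(pca50 = 5.8, n_h = 2, floor = 0, ceiling = 1,
                          noise_sd = 0.02,
                          pca_grid = c(4.50, 5.11, 5.42, 5.61, 5.77, 6.00,
                                       10.00),
                          seed, fiber_id = "synthetic") {
  stopifnot(noise_sd >= 0)
  set.seed(seed)
  mu <- floor + (ceiling - floor) / (1 + 10^(n_h * (pca_grid - pca50)))
  force <- pmax(mu + stats::rnorm(length(pca_grid), 0, noise_sd), 0)
  structure(data.frame(fiber_id = fiber_id, pca = pca_grid, force = force),
            ground_truth = list(pca50 = pca50, n_h = n_h, floor = floor,
                                ceiling = ceiling, noise_sd = noise_sd,
                                seed = seed))
}

#' Default ground-truth parameters of the synthetic motility assay
#'
#' The generator emulates tracked thin filaments in a motility flow cell:
#' a calcium-dependent logistic sets the mobile probability, fragment
#' binding adds Ca-independent activation, mobile filaments slide at
#' `v0 * (1 - drag * theta)` with per-filament speed variability, and all
#' positions carry Gaussian localisation jitter (95 nm per frame,
#' reflecting the camera pixel scale). Movies are acquired at 10 frame/s
#' and analysed after down-sampling to 2 frame/s.
#'
#' @return Named list of generator parameters.
#' @export
motility_truth <- function() {
  list(v0 = 5,             # um/s, uninhibited sliding speed
       speed_cv = 0.1,     # per-filament speed coefficient of variation
       pca50_mobile = 6.25,  # pCa at half-maximal mobile probability
       n_mobile = 2,       # steepness of the calcium dependence
       p_max = 0.9,        # mobile probability at saturating calcium
       p_base = 0.02,      # spontaneous mobile probability
       jitter_sd = 0.095,  # um, localisation noise per frame per axis
       frame_rate = 10,    # Hz acquisition
       n_frames = 41,      # frames per track (4 s of imaging)
       analysis_rate = 2,  # Hz after down-sampling
       n_movies = 3)       # triplicate movies per condition
}

#' Generate synthetic filament tracks for a manifest of conditions
#'
#' For each condition (a pCa, an isoform and a fragment dose) filaments
#' are mobile with probability
#' `p_base + (p_max - p_base) * (L + theta * act_rel * (1 - L))`, where
#' `L` is the calcium logistic and `theta` the fragment occupancy from the
#' isoform's [isoform_defaults()]; `act_rel = k_act / 20` scales the
#' Ca-independent activation. Mobile filaments move in a random fixed
#' direction at `v0 * (1 - drag * theta)` (per-filament lognormal-free
#' Gaussian speed spread, truncated at 0); immobile filaments are
#' stationary. Every position carries independent Gaussian localisation
#' jitter.
#'
#' @param conditions data.frame with columns `pca`, `isoform`,
#'   `frag_conc` (M); one row per condition.
#' @param truth Generator parameters, see [motility_truth()].
#' @param n_filaments Filaments per condition (split across movies).
#' @param seed Integer seed.
#' @return Tracks data.frame (`movie_id`, `filament_id`, `frame`, `t`,
#'   `x_um`, `y_um`) with columns `pca`, `isoform`, `frag_conc` carried
#'   per row and the full ground truth in attribute `ground_truth`.
#' @export
gen_tracks <- function(conditions, truth = motility_truth(),
                       n_filaments = 300, seed) {
  stopifnot(is.data.frame(conditions),
            all(c("pca", "isoform", "frag_conc") %in% names(conditions)),
            n_filaments >= 1)
  set.seed(seed)
  tt <- (seq_len(truth$n_frames) - 1) / truth$frame_rate
  out <- list()
  for (ci in seq_len(nrow(conditions))) {
    pca <- conditions$pca[ci]
    iso <- as.character(conditions$isoform[ci])
    frag <- conditions$frag_conc[ci]
    e <- isoform_defaults(iso)
    theta <- frag_occupancy(e, frag)
    act_rel <- e$k_act / 20
    L <- 1 / (1 + 10^(truth$n_mobile * (pca - truth$pca50_mobile)))
    p_mobile <- truth$p_base +
      (truth$p_max - truth$p_base) * (L + theta * act_rel * (1 - L))
    v_cond <- truth$v0 * (1 - e$drag * theta)
    movie <- rep_len(seq_len(truth$n_movies), n_filaments)
    rows <- lapply(seq_len(n_filaments), function(fi) {
      mobile <- stats::runif(1) < p_mobile
      x0 <- stats::runif(1, 0, 80)
      y0 <- stats::runif(1, 0, 80)
      if (mobile) {
        v <- max(0, stats::rnorm(1, v_cond, truth$speed_cv * v_cond))
        ang <- stats::runif(1, 0, 2 * pi)
        x <- x0 + v * cos(ang) * tt
        y <- y0 + v * sin(ang) * tt
      } else {
        x <- rep(x0, truth$n_frames)
        y <- rep(y0, truth$n_frames)
      }
      x <- x + stats::rnorm(truth$n_frames, 0, truth$jitter_sd)
      y <- y + stats::rnorm(truth$n_frames, 0, truth$jitter_sd)
      data.frame(movie_id = sprintf("c%d_m%d", ci, movie[fi]),
                 filament_id = sprintf("c%d_f%d", ci, fi),
                 frame = seq_len(truth$n_frames) - 1L,
                 t = tt, x_um = x, y_um = y,
                 pca = pca, isoform = iso, frag_conc = frag)
    })
    out[[ci]] <- do.call(rbind, rows)
  }
  structure(do.call(rbind, out),
            ground_truth = c(truth, list(seed = seed,
                                         conditions = conditions)))
}

#' Analyse generated tracks the way the motility pipeline would
#'
#' Convenience wrapper: down-samples every track to the analysis rate and
#' computes the [motility_statistic()]. Used by round-trip tests and the
#' acceptance analyses.
#'
#' @param df Tracks data.frame from [gen_tracks()] (one condition).
#' @param analysis_rate Frame rate after down-sampling (Hz).
#' @param ... Passed to [motility_statistic()].
#' @return A `motility_stat`.
#' @export
analyze_tracks <- function(df, analysis_rate = 2, ...) {
  tracks <- tracks_from_df(df)
  tracks <- lapply(tracks, downsample_track, target_rate = analysis_rate)
  motility_statistic(tracks, ...)
}

#' Generate a synthetic tension-redevelopment trace
#'
#' `y(t) = offset + amplitude (1 - exp(-rate t))` plus Gaussian noise.
#'
#' @param rate Redevelopment rate constant (s^-1).
#' @param noise_sd Gaussian noise SD.
#' @param duration Trace length (s).
#' @param seed Integer seed.
#' @param dt Sampling interval (s).
#' @param amplitude,offset Curve parameters.
#' @return A [new_trace()] with the generating parameters in
#'   `ground_truth`.
#' @export
gen_ktr_trace <- function(rate, noise_sd = 0, duration = 2, seed,
                          dt = 0.002, amplitude = 1, offset = 0) {
  stopifnot(rate >= 0, noise_sd >= 0, duration > 0)
  set.seed(seed)
  tt <- seq(0, duration, by = dt)
  y <- offset + amplitude * (1 - exp(-rate * tt)) +
    stats::rnorm(length(tt), 0, noise_sd)
  tr <- new_trace(tt, y, units = "force",
                  meta = list(seed = seed, rate = rate))
  attr(tr, "ground_truth") <- list(rate = rate, amplitude = amplitude,
                                   offset = offset, noise_sd = noise_sd,
                                   seed = seed)
  tr
}

#' Generate a synthetic NADH absorbance trace with ADP calibration steps
#'
#' Baseline absorbance declines at `rate * calib` AU/s (NADH oxidation
#' stoichiometrically coupled to ATP consumption); each injection of
#' `inj_moles` mol ADP drops the absorbance by `calib * inj_moles` AU. The
#' default injection is 50 nl of 10 mM ADP = 5e-10 mol.
#'
#' @param rate True ATPase rate (mol/s).
#' @param calib Calibration factor (AU per mol NADH).
#' @param seed Integer seed.
#' @param inj_times Injection times (s).
#' @param inj_moles Moles of ADP per injection.
#' @param noise_sd Gaussian absorbance noise SD (AU).
#' @param duration,dt Trace extent and sampling (s).
#' @param a0 Initial absorbance (AU).
#' @return A [new_trace()] with attribute `injections` (data.frame
#'   `time`, `moles`) and the generating parameters in `ground_truth`.
#' @export
gen_nadh_trace <- function(rate, calib = 4e7, seed,
                           inj_times = c(70, 90), inj_moles = 5e-10,
                           noise_sd = 0, duration = 120, dt = 0.1,
                           a0 = 1.5) {
  stopifnot(rate >= 0, calib > 0, noise_sd >= 0)
  set.seed(seed)
  tt <- seq(0, duration, by = dt)
  y <- a0 - rate * calib * tt
  for (t0 in inj_times) y <- y - ifelse(tt > t0, calib * inj_moles, 0)
  y <- y + stats::rnorm(length(tt), 0, noise_sd)
  tr <- new_trace(tt, y, units = "AU",
                  meta = list(seed = seed, rate = rate, calib = calib))
  attr(tr, "injections") <- data.frame(time = inj_times,
                                       moles = rep(inj_moles,
                                                   length(inj_times)))
  attr(tr, "ground_truth") <- list(rate = rate, calib = calib,
                                   noise_sd = noise_sd, seed = seed)
  tr
}

#' Generate a paced sarcomere-length twitch trace
#'
#' Beats are paced at 1 Hz. Each beat shortens along a half-cosine to its
#' peak deflection and recovers as a single exponential with time constant
#' `tau`, so the matching analysers recover `tau` and the
#' time-to-%-baseline values in closed form.
#'
#' @param sl_rest Resting sarcomere length (um).
#' @param peak_shortening Peak deflection as a fraction of `sl_rest`.
#' @param t_peak Time from stimulus to peak shortening (s).
#' @param tau Relaxation time constant (s).
#' @param n_beats Number of paced beats.
#' @param period Pacing interval (s).
#' @param pre Pre-stimulus baseline recorded before the first beat (s).
#' @param noise_sd Gaussian SL noise SD (um).
#' @param seed Integer seed.
#' @param dt Sampling interval (s).
#' @return A [new_trace()] of SL (um) with `stim_times` in its metadata
#'   and the generating parameters in `ground_truth`.
#' @export
gen_twitch <- function(sl_rest = 1.8, peak_shortening = 0.08, t_peak = 0.06,
                       tau = 0.15, n_beats = 10, period = 1, pre = 0.2,
                       noise_sd = 0, seed, dt = 0.004) {
  stopifnot(sl_rest > 0, peak_shortening > 0, peak_shortening < 1,
            t_peak > 0, tau > 0, n_beats >= 1, noise_sd >= 0)
  set.seed(seed)
  amp <- peak_shortening * sl_rest
  total <- pre + n_beats * period
  tt <- seq(0, total, by = dt)
  stim_times <- pre + (seq_len(n_beats) - 1) * period
  y <- rep(sl_rest, length(tt))
  for (s in stim_times) {
    rel <- tt - s
    rise <- rel >= 0 & rel < t_peak
    fall <- rel >= t_peak & rel < period
    y[rise] <- sl_rest - amp * (1 - cos(pi * rel[rise] / t_peak)) / 2
    y[fall] <- sl_rest - amp * exp(-(rel[fall] - t_peak) / tau)
  }
  y <- y + stats::rnorm(length(tt), 0, noise_sd)
  tr <- new_trace(tt, y, units = "um",
                  meta = list(seed = seed, pacing_hz = 1 / period,
                              stim_times = stim_times))
  attr(tr, "ground_truth") <- list(sl_rest = sl_rest,
                                   peak_shortening = peak_shortening,
                                   t_peak = t_peak, tau = tau,
                                   noise_sd = noise_sd, seed = seed,
                                   stim_times = stim_times)
  tr
}
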