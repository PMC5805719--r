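#' Average paced twitches into one representative beat
#'
#' Aligns sarcomere-length epochs on their stimulus times and averages them
#' pointwise, the standard treatment of 10 paced contractions per myocyte.
#' Each epoch spans `pre` seconds before to `post` seconds after its
#' stimulus; the averaged beat has the stimulus at `t = 0`.
#'
#' @param trace A [new_trace()] of sarcomere length (um).
#' @param stim_times Stimulus times (s), >= 2, uniformly paced.
#' @param pre Pre-stimulus window retained for the baseline (s).
#' @param post Post-stimulus window (s); defaults to the pacing interval
#'   minus `pre`.
#' @return A [new_trace()] of the averaged beat, stimulus at `t = 0`.
#' @export
average_beats <- function(trace, stim_times, pre = 0.1, post = NULL) {
  stopifnot(inherits(trace, "trace"), is.numeric(stim_times))
  if (length(stim_times) < 2) {
    stop("average_beats needs >= 2 stimulus epochs", call. = FALSE)
  }
  dt <- trace_dt(trace)
  if (is.null(post)) post <- min(diff(sort(stim_times))) - pre
  n_pre <- as.integer(round(pre / dt))
  n_post <- as.integer(round(post / dt))
  n_epoch <- n_pre + n_post + 1L
  t0 <- trace$t[1]
  epochs <- lapply(stim_times, function(s) {
    i_stim <- as.integer(round((s - t0) / dt)) + 1L
    idx <- (i_stim - n_pre):(i_stim + n_post)
    if (idx[1] < 1L || idx[n_epoch] > nrow(trace)) {
      stop("stimulus epoch at t = ", s, " s extends beyond the trace",
           call. = FALSE)
    }
    trace$y[idx]
  })
  lens <- lengths(epochs)
  if (length(unique(lens)) != 1L) {
    stop("mismatched epoch lengths", call. = FALSE)
  }
  avg <- Reduce(`+`, epochs) / length(epochs)
  new_trace(seq(-n_pre, n_post) * dt, avg, units = attr(trace, "units"),
            meta = c(attr(trace, "meta"),
                     list(n_beats = length(stim_times))))
}

#' Relaxation time constant from the log-linear fit
#'
#' The relaxation constant tau is obtained from a logarithmic fit of the
#' recovery limb: linear regression of `log(sl_rest - SL)` against time
#' over the segment from peak shortening to the end of the beat, with
#' `tau = -1/slope`. Samples whose deflection has fallen to the noise
#' floor are excluded. A direct nonlinear exponential fit
#' (`method = "nls"`) is provided as a cross-check; the two agree on clean
#' exponential recoveries.
#'
#' @param beat A single-beat [new_trace()] of sarcomere length (um),
#'   stimulus at `t = 0` (pre-stimulus samples at negative t are used for
#'   the baseline).
#' @param sl_rest Resting sarcomere length; defaults to the median over
#'   the 100 ms before the stimulus.
#' @param noise_floor Deflection level (um) below which samples are
#'   excluded; defaults to 5% of the peak deflection or three times the
#'   pre-stimulus noise SD, whichever is larger. The fitted segment stops
#'   at the first sample that reaches the floor, so the flat noise tail
#'   never enters the regression.
#' @param method `"loglinear"` (default) or `"nls"`.
#' @return List with `tau` (s), `low_confidence` (TRUE when the usable
#'   recovery spans less than one tau) and `n_used`.
#' @export
fit_relaxation_tau <- function(beat, sl_rest = NULL, noise_floor = NULL,
                               method = c("loglinear", "nls")) {
  method <- match.arg(method)
  stopifnot(inherits(beat, "trace"))
  if (is.null(sl_rest)) sl_rest <- baseline_sl(beat)
  post <- beat$t >= 0
  i_peak <- which(post)[which.min(beat$y[post])]
  seg_t <- beat$t[i_peak:nrow(beat)]
  seg_d <- sl_rest - beat$y[i_peak:nrow(beat)]
  if (length(seg_t) < 10) {
    stop("fit_relaxation_tau needs >= 10 samples after peak shortening",
         call. = FALSE)
  }
  defl <- seg_d[1]
  if (defl <= 0) {
    stop("no shortening deflection to fit", call. = FALSE)
  }
  if (is.null(noise_floor)) {
    pre <- beat$t < 0 & beat$t >= -0.1
    noise_est <- if (sum(pre) >= 5) stats::sd(beat$y[pre]) else 0
    noise_floor <- max(0.05 * defl, 3 * noise_est)
  }
  use <- seg_d > noise_floor
  # keep only the contiguous recovery limb before the floor is reached
  first_below <- which(!use)[1]
  if (!is.na(first_below)) use[first_below:length(use)] <- FALSE
  if (sum(use) < 5) {
    stop("fewer than 5 usable samples above the noise floor", call. = FALSE)
  }
  tt <- seg_t[use]; dd <- seg_d[use]
  tau <- if (method == "loglinear") {
    slope <- stats::coef(stats::lm(log(dd) ~ tt))[[2]]
    if (slope >= 0) stop("deflection does not decay: tau undefined",
                         call. = FALSE)
    -1 / slope
  } else {
    fit <- minpack.lm::nlsLM(dd ~ A * exp(-tt / tau),
                             start = list(A = defl,
                                          tau = max(diff(range(tt)) / 3,
                                                    1e-3)),
                             lower = c(A = 0, tau = 1e-6))
    stats::coef(fit)[["tau"]]
  }
  list(tau = tau,
       low_confidence = diff(range(tt)) < tau,
       n_used = sum(use))
}

# Baseline: median of the 100 ms before the stimulus; if the beat carries
# no pre-stimulus samples, fall back to its first sample.
baseline_sl <- function(beat, window = 0.1) {
  pre <- beat$t < 0 & beat$t >= -window
  if (any(pre)) stats::median(beat$y[pre]) else beat$y[1]
}

#' Twitch metrics of an averaged unloaded-shortening beat
#'
#' Computes resting sarcomere length (pre-stimulus median), peak
#' shortening, time of peak, times to 10/50/90% recovery of the deflection
#' toward resting SL (linearly interpolated between samples, measured from
#' the peak), and the relaxation constant tau from
#' [fit_relaxation_tau()]. "90% baseline" means 90% of the deflection
#' recovered. Recovery levels never reached within the beat are reported
#' as `NA` rather than extrapolated.
#'
#' @inheritParams fit_relaxation_tau
#' @return An object of class `twitch_metrics`: list with `sl_rest` (um),
#'   `peak_shortening` (% of resting SL), `t_peak` (s), `t_baseline_10`,
#'   `t_baseline_50`, `t_baseline_90` (s after peak), `tau` (s).
#' @export
twitch_metrics <- function(beat, sl_rest = NULL, noise_floor = NULL) {
  stopifnot(inherits(beat, "trace"))
  if (is.null(sl_rest)) sl_rest <- baseline_sl(beat)
  post <- which(beat$t >= 0)
  y <- beat$y[post]; tt <- beat$t[post]
  i_min <- which.min(y)
  defl <- sl_rest - y[i_min]
  if (defl <= 1e-9 * max(sl_rest, 1)) {
    stop("flat trace: no shortening peak", call. = FALSE)
  }
  t_peak <- tt[i_min]
  t_recover <- function(pct) {
    level <- sl_rest - (1 - pct / 100) * defl
    yr <- y[i_min:length(y)]; tr <- tt[i_min:length(y)]
    i <- which(yr >= level)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1L) return(0)
    # linear interpolation between the bracketing samples
    t_hit <- tr[i - 1] + (level - yr[i - 1]) * (tr[i] - tr[i - 1]) /
      (yr[i] - yr[i - 1])
    t_hit - t_peak
  }
  tau <- tryCatch(
    fit_relaxation_tau(beat, sl_rest = sl_rest,
                       noise_floor = noise_floor)$tau,
    error = function(e) NA_real_)
  structure(list(sl_rest = sl_rest,
                 peak_shortening = 100 * defl / sl_rest,
                 t_peak = t_peak,
                 t_baseline_10 = t_recover(10),
                 t_baseline_50 = t_recover(50),
                 t_baseline_90 = t_recover(90),
                 tau = tau),
            class = "twitch_metrics")
}

#' @export
print.twitch_metrics <- function(x, ...) {
  cat(sprintf(
    "<twitch_metrics> SL rest = %.3f um, peak shortening = %.2f%%, t_peak = %.3f s\n  t to 10/50/90%% baseline = %.4f / %.4f / %.4f s, tau = %.4f s\n",
    x$sl_rest, x$peak_shortening, x$t_peak, x$t_baseline_10,
    x$t_baseline_50, x$t_baseline_90, x$tau))
  invisible(x)
}

#' Replacement level from Western-blot densitometry
#'
#' Fraction of the MyBP-C pool replaced by the tagged construct:
#' `signal_myc / (signal_myc + signal_endog)`.
#'
#' @param signal_myc Densitometry signal of the cMyc-tagged construct.
#' @param signal_endog Densitometry signal of endogenous cMyBP-C.
#' @return Replacement fraction in `[0, 1]`.
#' @examples
#' replacement_level(30, 70)  # 0.30
#' @export
replacement_level <- function(signal_myc, signal_endog) {
  stopifnot(is.numeric(signal_myc), is.numeric(signal_endog))
  if (any(signal_myc < 0) || any(signal_endog < 0)) {
    stop("densitometry signals must be >= 0", call. = FALSE)
  }
  tot <- signal_myc + signal_endog
  if (any(tot == 0)) {
    stop("both signals are zero: replacement level undefined", call. = FALSE)
  }
  signal_myc / tot
}
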