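# Closed-form quadratic root of the 1:1 Ca-EGTA equilibrium:
# free^2 + (K + E_t - Ca_t) free - K Ca_t = 0, positive root.
# Independent oracle for the bisection solver.
quadratic_free_ca <- function(total_ca, total_egta, kd_app) {
  b <- kd_app + total_egta - total_ca
  disc <- sqrt(b^2 + 4 * kd_app * total_ca)
  # numerically stable positive root (avoids cancellation when b > 0)
  if (b > 0) 2 * kd_app * total_ca / (b + disc) else (disc - b) / 2
}

# Straight noiseless track moving at constant speed (um/s)
straight_track <- function(v, frame_rate, n_frames, id = "f1",
                           movie_id = NA) {
  tt <- (seq_len(n_frames) - 1) / frame_rate
  filament_track(id, x = v * tt, y = rep(0, n_frames),
                 frame_rate = frame_rate, movie_id = movie_id)
}

# Ideal single beat: flat baseline, instantaneous drop at the stimulus,
# exponential recovery with time constant tau.
ideal_beat <- function(sl_rest = 1.8, amp = 0.15, tau = 0.2, dt = 0.002,
                       pre = 0.2, post = 1.5) {
  tt <- seq(-pre, post, by = dt)
  y <- ifelse(tt < 0, sl_rest, sl_rest - amp * exp(-tt / tau))
  new_trace(tt, y, units = "um")
}
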