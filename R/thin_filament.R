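#' Kinetic parameters of the thin-filament regulatory chain
#'
#' Each regulatory unit (an actin7-tropomyosin-troponin span) moves between
#' three tropomyosin positions: blocked (B), closed (C) and myosin-bound
#' (M). Calcium binding to troponin is treated as an instantaneous Hill
#' equilibrium that scales the B->C rate; neighbouring units couple
#' cooperatively along the filament.
#'
#' @param n_units Number of regulatory units in the chain (default 26, one
#'   thin filament strand).
#' @param k_on_max Maximal calcium-driven B->C rate, the tropomyosin shift
#'   rate at saturating Ca2+ (s^-1).
#' @param k_off C->B rate (s^-1).
#' @param f_app Apparent crossbridge attachment rate C->M (s^-1).
#' @param g_app Apparent crossbridge detachment rate M->C (s^-1).
#' @param gamma Nearest-neighbour coupling factor (>= 1, dimensionless):
#'   B->C is multiplied and C->B divided by `gamma` per active (C or M)
#'   neighbour.
#' @param ca50_tn Free Ca2+ at half troponin occupancy (M).
#' @param n_tn Hill exponent of the troponin calcium occupancy.
#'
#' @return An object of class `thin_filament_params`.
#' @export
thin_filament_params <- function(n_units = 26L, k_on_max = 50, k_off = 100,
                                 f_app = 10, g_app = 10, gamma = 2,
                                 ca50_tn = 5e-6, n_tn = 1) {
  p <- list(n_units = as.integer(n_units), k_on_max = k_on_max,
            k_off = k_off, f_app = f_app, g_app = g_app, gamma = gamma,
            ca50_tn = ca50_tn, n_tn = n_tn)
  rates <- c(p$k_on_max, p$k_off, p$f_app, p$g_app)
  if (any(!is.finite(unlist(p))) || any(rates < 0) || p$gamma < 1 ||
      p$n_units < 1L || p$ca50_tn <= 0 || p$n_tn <= 0) {
    stop("invalid thin_filament_params: rates >= 0, gamma >= 1, ",
         "n_units >= 1, ca50_tn > 0, n_tn > 0", call. = FALSE)
  }
  structure(p, class = "thin_filament_params")
}

#' MyBP-C isoform effect on thin-filament kinetics
#'
#' An N-terminal MyBP-C fragment binds the thin filament with dissociation
#' constant `kd_frag`; at fractional occupancy theta it adds a
#' calcium-independent B->C rate `theta * k_act` (activation even at pCa 9,
#' where troponin is empty) and multiplies sliding velocity by
#' `1 - drag * theta` (crossbridge drag, applied only in sliding/twitch
#' contexts because isometric force at saturating Ca2+ is unaffected).
#'
#' @param isoform One of `"cardiac"`, `"slow_skeletal"`, `"fast_skeletal"`,
#'   `"none"`.
#' @param k_act Ca-independent B->C rate added at saturating fragment
#'   (s^-1).
#' @param drag Fractional velocity inhibition at saturating fragment, in
#'   `[0, 1]`.
#' @param kd_frag Fragment binding constant (M).
#' @return An object of class `isoform_effect`.
#' @seealso [isoform_defaults()] for the built-in parameter sets.
#' @export
isoform_effect <- function(isoform = c("none", "cardiac", "slow_skeletal",
                                       "fast_skeletal"),
                           k_act = 0, drag = 0, kd_frag = 1e-6) {
  isoform <- match.arg(isoform)
  if (!is.finite(k_act) || k_act < 0 || !is.finite(drag) || drag < 0 ||
      drag > 1 || !is.finite(kd_frag) || kd_frag <= 0) {
    stop("invalid isoform_effect: k_act >= 0, drag in [0, 1], kd_frag > 0",
         call. = FALSE)
  }
  structure(list(isoform = isoform, k_act = k_act, drag = drag,
                 kd_frag = kd_frag),
            class = "isoform_effect")
}

#' Default MyBP-C isoform parameter sets
#'
#' Declared model fixtures, fixed once so that the qualitative isoform
#' orderings hold: activation capacity cardiac > slow-skeletal >
#' fast-skeletal, and velocity drag cardiac ~ fast-skeletal >>
#' slow-skeletal. The cardiac pair (`drag`, `kd_frag`) is set so that at a
#' 0.25 uM fragment dose the encoded velocity inhibition at saturating
#' calcium is 43%.
#'
#' @param isoform Isoform name; see [isoform_effect()].
#' @return An [isoform_effect()] object.
#' @examples
#' e <- isoform_defaults("cardiac")
#' theta <- 0.25e-6 / (0.25e-6 + e$kd_frag)
#' e$drag * theta  # encoded high-Ca velocity inhibition: 0.43
#' @export
isoform_defaults <- function(isoform = c("none", "cardiac", "slow_skeletal",
                                         "fast_skeletal")) {
  isoform <- match.arg(isoform)
  switch(isoform,
    cardiac       = isoform_effect("cardiac", k_act = 15, drag = 0.516,
                                   kd_frag = 5e-8),
    slow_skeletal = isoform_effect("slow_skeletal", k_act = 10, drag = 0.10,
                                   kd_frag = 5e-8),
    fast_skeletal = isoform_effect("fast_skeletal", k_act = 2, drag = 0.50,
                                   kd_frag = 1e-7),
    none          = isoform_effect("none", k_act = 0, drag = 0,
                                   kd_frag = 1e-6))
}

#' Fragment occupancy of the thin filament
#'
#' Simple binding isotherm `theta = frag / (frag + kd_frag)`.
#'
#' @param e An [isoform_effect()].
#' @param frag_conc Fragment concentration (M).
#' @return Fractional occupancy in `[0, 1]`.
#' @export
frag_occupancy <- function(e, frag_conc) {
  stopifnot(inherits(e, "isoform_effect"))
  if (!is.finite(frag_conc) || frag_conc < 0) {
    stop("frag_conc must be finite and >= 0", call. = FALSE)
  }
  frag_conc / (frag_conc + e$kd_frag)
}

#' Per-unit transition rates at given calcium and fragment dose
#'
#' The B->C rate combines the troponin-gated calcium pathway with the
#' Ca-independent fragment pathway:
#' \deqn{a = k_{on,max} \frac{Ca^{n}}{Ca^{n} + Ca_{50}^{n}} + \theta k_{act}}
#' with `b = k_off`, `f = f_app`, `g = g_app` unchanged.
#'
#' @param p A [thin_filament_params()].
#' @param e An [isoform_effect()].
#' @param frag_conc Fragment concentration (M).
#' @param ca Free Ca2+ concentration (M).
#' @return List with elements `a`, `b`, `f`, `g`, `theta`.
#' @export
effective_rates <- function(p, e, frag_conc, ca) {
  stopifnot(inherits(p, "thin_filament_params"))
  if (!is.numeric(ca) || any(!is.finite(ca)) || any(ca < 0)) {
    stop("ca must be finite and >= 0", call. = FALSE)
  }
  theta <- frag_occupancy(e, frag_conc)
  hill <- ca^p$n_tn / (ca^p$n_tn + p$ca50_tn^p$n_tn)
  hill[ca == 0] <- 0  # guard 0/0 when ca = 0
  list(a = p$k_on_max * hill + theta * e$k_act,
       b = p$k_off, f = p$f_app, g = p$g_app, theta = theta)
}

#' Analytic steady state of a single uncoupled regulatory unit
#'
#' Flux balance on the linear chain B <-> C <-> M gives
#' `pi_C = pi_B a/b` and `pi_M = pi_B a f /(b g)`, normalised to sum 1.
#' Absorbing limits (`b = 0` or `g = 0`) return the absorbed distribution
#' rather than erroring. Serves as the analytic oracle for the stochastic
#' simulator at `gamma = 1`.
#'
#' @param rates List with elements `a`, `b`, `f`, `g` (s^-1).
#' @return Named numeric vector `c(pi_b, pi_c, pi_m)` summing to 1.
#' @export
steady_state_single_unit <- function(rates) {
  a <- rates$a; b <- rates$b; f <- rates$f; g <- rates$g
  stopifnot(all(is.finite(c(a, b, f, g))), all(c(a, b, f, g) >= 0))
  out <- if (a == 0) {
    c(1, 0, 0)
  } else if (b == 0) {
    # B drains; C <-> M balance remains
    if (f == 0) c(0, 1, 0)
    else if (g == 0) c(0, 0, 1)
    else c(0, g, f) / (f + g)
  } else if (g == 0) {
    if (f == 0) c(b, a, 0) / (a + b) else c(0, 0, 1)
  } else {
    w <- c(1, a / b, a * f / (b * g))
    w / sum(w)
  }
  names(out) <- c("pi_b", "pi_c", "pi_m")
  out
}

# Shared guard: fixed-step kMC is only valid when every per-step exit
# probability stays small.  Worst case: a unit in B with two active
# neighbours, or a unit in C with no active neighbours.
check_dt_stability <- function(a_max, p, dt) {
  exit_max <- max(a_max * p$gamma^2, p$k_off + p$f_app, p$g_app)
  if (exit_max * dt > 0.1 + 1e-12) {
    stop(sprintf(
      "dt = %g violates the stability guard (max exit rate %.3g /s): need dt <= %.3g s",
      dt, exit_max, 0.1 / exit_max), call. = FALSE)
  }
  invisible(TRUE)
}

run_chain <- function(p, a_base, state0) {
  chain_sim_cpp(state0, a_base, p$k_off, p$f_app, p$g_app, p$gamma,
                attr(a_base, "dt"))
}

#' Simulate the cooperative regulatory chain at fixed calcium
#'
#' Fixed-timestep kinetic Monte Carlo of `n_units` coupled units. The force
#' proxy is the fraction of units in the myosin-bound state M. Identical
#' `(params, seed)` give bit-identical trajectories.
#'
#' @param p A [thin_filament_params()].
#' @param e An [isoform_effect()].
#' @param frag_conc Fragment concentration (M).
#' @param ca Free Ca2+ concentration (M).
#' @param duration Simulated time (s).
#' @param dt Time step (s); must satisfy max exit rate * dt <= 0.1.
#' @param seed Integer seed for the run's random stream.
#' @param state0 Optional initial unit states (integer vector, 0 = B,
#'   1 = C, 2 = M); defaults to all blocked.
#' @return A [new_trace()] of the M-state fraction over time, with the
#'   final unit states in the `state` attribute.
#' @export
simulate_chain <- function(p, e = isoform_defaults("none"), frag_conc = 0,
                           ca, duration, dt = 1e-4, seed = 1L,
                           state0 = NULL) {
  stopifnot(inherits(p, "thin_filament_params"), duration > 0, dt > 0)
  r <- effective_rates(p, e, frag_conc, ca)
  check_dt_stability(r$a, p, dt)
  n_steps <- max(2L, as.integer(round(duration / dt)))
  a_base <- rep(r$a, n_steps)
  attr(a_base, "dt") <- dt
  if (is.null(state0)) state0 <- integer(p$n_units)
  set.seed(seed)
  sim <- run_chain(p, a_base, state0)
  tr <- new_trace(t = seq_len(n_steps) * dt, y = sim$pi_m,
                  units = "fraction",
                  meta = list(seed = seed, dt = dt, ca = ca,
                              frag_conc = frag_conc, isoform = e$isoform))
  attr(tr, "state") <- sim$state
  attr(tr, "pi_b") <- sim$pi_b
  attr(tr, "pi_c") <- sim$pi_c
  tr
}

#' Steady-state force-pCa curve of the simulated chain
#'
#' Runs [simulate_chain()] at each pCa and averages the M-state fraction
#' over the second half of the run (the first half is discarded as burn-in).
#'
#' @inheritParams simulate_chain
#' @param pca_grid pCa values to simulate.
#' @param dt Time step (s), or `"auto"` to use the largest step the
#'   stability guard allows at each pCa (capped at 1e-4 s).
#' @param normalized If `TRUE`, divide by the value at the lowest pCa
#'   (highest calcium).
#' @param burn_in Fraction of each run discarded before averaging.
#' @param n_reps Independent replicate runs averaged per pCa.
#' @return data.frame with columns `pca` and `pi_m` (mean M-state
#'   fraction, the relative-force proxy).
#' @export
force_pca_curve <- function(p, e = isoform_defaults("none"), frag_conc = 0,
                            pca_grid, duration = 10, dt = 1e-4, seed = 1L,
                            normalized = FALSE, burn_in = 0.5,
                            n_reps = 1L) {
  stopifnot(length(pca_grid) >= 1, all(is.finite(pca_grid)))
  pi_m <- vapply(seq_along(pca_grid), function(i) {
    ca <- 10^(-pca_grid[i])
    dt_i <- if (identical(dt, "auto")) {
      r <- effective_rates(p, e, frag_conc, ca)
      exit_max <- max(r$a * p$gamma^2, r$b + r$f, r$g)
      min(1e-4, 0.1 / exit_max)
    } else dt
    reps <- vapply(seq_len(n_reps), function(k) {
      tr <- simulate_chain(p, e, frag_conc, ca = ca,
                           duration = duration, dt = dt_i,
                           seed = seed + (i - 1L) * n_reps + k - 1L)
      mean(tr$y[tr$t > burn_in * duration])
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  if (normalized) {
    ref <- pi_m[which.min(pca_grid)]
    if (ref <= 0) stop("cannot normalize: zero response at minimum pCa",
                       call. = FALSE)
    pi_m <- pi_m / ref
  }
  data.frame(pca = pca_grid, pi_m = pi_m)
}

#' Release-restretch (k_tr) protocol
#'
#' Runs the chain to steady state, then at the release instant detaches
#' every bound crossbridge (all M units set to C; tropomyosin states are
#' otherwise untouched) and follows the redevelopment of the M-state
#' fraction. The returned trace is aligned so `t = 0` is the release;
#' pre-release samples carry negative times.
#'
#' @inheritParams simulate_chain
#' @param t_release Time of the release (s), `0 < t_release < duration`.
#' @return A [new_trace()] of the M-state fraction, release at `t = 0`.
#' @export
simulate_ktr <- function(p, e = isoform_defaults("none"), frag_conc = 0,
                         ca, t_release, duration, dt = 1e-4, seed = 1L) {
  stopifnot(t_release > 0, t_release < duration)
  r <- effective_rates(p, e, frag_conc, ca)
  check_dt_stability(r$a, p, dt)
  n_pre <- as.integer(round(t_release / dt))
  n_post <- as.integer(round((duration - t_release) / dt))
  a_pre <- rep(r$a, n_pre); attr(a_pre, "dt") <- dt
  a_post <- rep(r$a, n_post); attr(a_post, "dt") <- dt
  set.seed(seed)
  pre <- run_chain(p, a_pre, integer(p$n_units))
  state <- pre$state
  state[state == 2L] <- 1L  # mechanical detachment: M -> C
  post <- run_chain(p, a_post, state)
  tt <- c(seq_len(n_pre) * dt - t_release - dt, 0,
          seq_len(n_post) * dt)
  yy <- c(pre$pi_m, 0, post$pi_m)  # t = 0: just after detachment
  new_trace(tt, yy, units = "fraction",
            meta = list(seed = seed, dt = dt, ca = ca,
                        frag_conc = frag_conc, t_release = t_release))
}

#' Idealised intracellular calcium transient
#'
#' Difference-of-exponentials drive for the twitch protocol:
#' `Ca(t) = Ca_dia + A (exp(-t/tau_decay) - exp(-t/tau_rise))`, with the
#' amplitude set so the maximum equals the peak calcium and
#' `Ca(0) = Ca_dia`.
#'
#' @param t_grid Uniform time grid (s) starting at 0.
#' @param pca_dia Diastolic pCa (must be >= `pca_peak`).
#' @param pca_peak Systolic (peak) pCa.
#' @param tau_rise,tau_decay Rise and decay time constants (s);
#'   `tau_rise < tau_decay`.
#' @return A [new_trace()] of free Ca2+ (M) over `t_grid`.
#' @export
ca_transient <- function(t_grid, pca_dia = 7, pca_peak = 5.8,
                         tau_rise = 0.03, tau_decay = 0.15) {
  stopifnot(is.numeric(t_grid), length(t_grid) >= 2)
  if (tau_rise >= tau_decay) {
    stop("tau_rise must be < tau_decay", call. = FALSE)
  }
  if (pca_dia < pca_peak) {
    stop("pca_dia must be >= pca_peak (diastolic calcium below peak)",
         call. = FALSE)
  }
  ca_dia <- 10^(-pca_dia)
  ca_peak <- 10^(-pca_peak)
  if (pca_dia == pca_peak) {
    return(new_trace(t_grid, rep(ca_dia, length(t_grid)), units = "M"))
  }
  t_max <- log(tau_decay / tau_rise) * tau_rise * tau_decay /
    (tau_decay - tau_rise)
  h <- function(t) exp(-t / tau_decay) - exp(-t / tau_rise)
  amp <- (ca_peak - ca_dia) / h(t_max)
  new_trace(t_grid, ca_dia + amp * h(t_grid), units = "M",
            meta = list(pca_dia = pca_dia, pca_peak = pca_peak,
                        tau_rise = tau_rise, tau_decay = tau_decay))
}

#' Unloaded sarcomere-shortening twitch
#'
#' Drives the regulatory chain with a time-varying calcium transient and
#' integrates the unloaded sarcomere-length dynamics
#' \deqn{dSL/dt = -v_{max}(1 - drag\,\theta)\,\pi_M(t) + k_{restore}(SL_{rest} - SL)}
#' by forward Euler on the simulation grid. Force-dependent terms are
#' absent by construction: the myocyte is unloaded, so shortening velocity
#' is set by actomyosin sliding and a passive restoring force returns the
#' sarcomere to rest.
#'
#' @inheritParams simulate_chain
#' @param transient A [ca_transient()] trace (free Ca2+ in M); interpolated
#'   onto the simulation grid.
#' @param sl_rest Resting sarcomere length (um).
#' @param v_max Maximal unloaded shortening velocity (um/s).
#' @param k_restore Passive restoring rate constant (s^-1).
#' @param pi_m Optional trace or numeric vector overriding the simulated
#'   M-state fraction (used for closed-form checks of the SL dynamics).
#' @param lead_in Diastolic lead-in (s) simulated before the transient
#'   starts, so that baseline activation and sarcomere length are
#'   pre-equilibrated at the diastolic calcium; the returned trace keeps
#'   these samples at negative times with the transient start at `t = 0`.
#'   Ignored when `pi_m` is supplied.
#' @return A [new_trace()] of sarcomere length (um); the underlying
#'   M-state fraction is attached as attribute `pi_m`.
#' @export
simulate_twitch <- function(p, e = isoform_defaults("none"), frag_conc = 0,
                            transient, sl_rest = 1.8, v_max = 4,
                            k_restore = 12, dt = 1e-4, seed = 1L,
                            pi_m = NULL, lead_in = 0.5) {
  stopifnot(inherits(transient, "trace"), sl_rest > 0, v_max > 0,
            k_restore > 0)
  if (!is.null(pi_m)) lead_in <- 0
  duration <- max(transient$t)
  n_steps <- as.integer(round((lead_in + duration) / dt))
  tt <- seq_len(n_steps) * dt - lead_in
  theta <- frag_occupancy(e, frag_conc)
  if (is.null(pi_m)) {
    ca_t <- stats::approx(transient$t, transient$y, xout = tt,
                          rule = 2)$y
    hill <- ca_t^p$n_tn / (ca_t^p$n_tn + p$ca50_tn^p$n_tn)
    a_base <- p$k_on_max * hill + theta * e$k_act
    check_dt_stability(max(a_base), p, dt)
    attr(a_base, "dt") <- dt
    set.seed(seed)
    sim <- run_chain(p, a_base, integer(p$n_units))
    pim <- sim$pi_m
  } else {
    pim <- if (inherits(pi_m, "trace")) {
      stats::approx(pi_m$t, pi_m$y, xout = tt, rule = 2)$y
    } else {
      stopifnot(length(pi_m) == n_steps)
      pi_m
    }
  }
  v_slide <- v_max * (1 - e$drag * theta)
  sl <- numeric(n_steps)
  cur <- sl_rest
  for (i in seq_len(n_steps)) {
    cur <- cur + dt * (-v_slide * pim[i] + k_restore * (sl_rest - cur))
    sl[i] <- cur
  }
  tr <- new_trace(tt, sl, units = "um",
                  meta = list(seed = seed, dt = dt, sl_rest = sl_rest,
                              v_max = v_max, k_restore = k_restore,
                              isoform = e$isoform, frag_conc = frag_conc))
  attr(tr, "pi_m") <- pim
  tr
}

#' Averaged unloaded-shortening beat over repeated twitches
#'
#' Simulates `n_beats` independent twitches with [simulate_twitch()] and
#' averages the sarcomere-length traces pointwise, mirroring the
#' experimental practice of averaging ten contractions per myocyte before
#' extracting relaxation metrics.
#'
#' @inheritParams simulate_twitch
#' @param n_beats Number of independent twitches averaged.
#' @return A [new_trace()] of the averaged beat (stimulus at `t = 0`).
#' @export
average_twitches <- function(p, e = isoform_defaults("none"),
                             frag_conc = 0, transient, n_beats = 10,
                             seed = 1L, ...) {
  beats <- lapply(seq_len(n_beats), function(k) {
    simulate_twitch(p, e, frag_conc, transient,
                    seed = seed * 1000L + k, ...)
  })
  new_trace(beats[[1]]$t,
            rowMeans(vapply(beats, function(b) b$y,
                            numeric(nrow(beats[[1]])))),
            units = "um",
            meta = list(seed = seed, n_beats = n_beats,
                        isoform = e$isoform, frag_conc = frag_conc))
}
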