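#' Fit a modified Hill (4-parameter logistic) force-pCa relation
#'
#' Least-squares fit of
#' \deqn{F(pCa) = floor + \frac{ceiling - floor}{1 + 10^{\,n_H (pCa - pCa_{50})}}}
#' the standard sigmoid of the fiber literature in pCa coordinates (base-10
#' exponent; reduces to the 2-parameter Hill curve when floor = 0,
#' ceiling = 1). Five deterministic Levenberg-Marquardt starts are run over
#' an n_H grid with the half-maximum crossing as the pCa50 start; the best
#' fit is chosen by lowest residual sum of squares, ties broken by lowest
#' n_H.
#'
#' @param pca pCa values (>= 4 distinct points).
#' @param force Response at each pCa (relative force, or any sigmoidal
#'   response such as the motility product).
#' @return An object of class `hill_fit`: list with `pca50`, `n_h`,
#'   `floor`, `ceiling`, `rss`, `fitted`.
#' @examples
#' grid <- c(4.50, 5.11, 5.42, 5.61, 5.77, 6.00, 10.00)
#' y <- 1 / (1 + 10^(2 * (grid - 5.8)))
#' fit_hill(grid, y)
#' @export
fit_hill <- function(pca, force) {
  stopifnot(is.numeric(pca), is.numeric(force), length(pca) == length(force))
  ok <- is.finite(pca) & is.finite(force)
  pca <- pca[ok]; force <- force[ok]
  if (length(unique(pca)) < 4) {
    stop("fit_hill needs >= 4 distinct pCa points", call. = FALSE)
  }
  span0 <- diff(range(force))
  if (span0 <= 1e-8 * max(abs(force), 1)) {
    stop("degenerate force-pCa data: response is constant (ceiling ~ floor)",
         call. = FALSE)
  }
  # half-maximum crossing as the pCa50 start
  o <- order(pca)
  ps <- pca[o]; fs <- force[o]
  half <- min(force) + span0 / 2
  idx <- which(diff(sign(fs - half)) != 0)
  pca50_0 <- if (length(idx)) {
    i <- idx[1]
    ps[i] + (half - fs[i]) * (ps[i + 1] - ps[i]) / (fs[i + 1] - fs[i])
  } else mean(range(pca))
  df <- data.frame(pca = pca, force = force)
  fits <- lapply(c(0.5, 1, 2, 4, 8), function(nh0) {
    tryCatch(
      minpack.lm::nlsLM(
        force ~ floor + span / (1 + 10^(n_h * (pca - pca50))),
        data = df,
        start = list(floor = min(force), span = span0,
                     n_h = nh0, pca50 = pca50_0),
        lower = c(floor = min(force) - span0, span = 0, n_h = 1e-6,
                  pca50 = min(pca) - 2),
        upper = c(floor = max(force), span = 3 * span0, n_h = 50,
                  pca50 = max(pca) + 2),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) {
    stop("Hill fit failed to converge from all starts (n = ",
         nrow(df), " points, response range ", signif(span0, 3), ")",
         call. = FALSE)
  }
  rss <- vapply(fits, stats::deviance, numeric(1))
  nh <- vapply(fits, function(f) stats::coef(f)[["n_h"]], numeric(1))
  best <- fits[[order(rss, nh)[1]]]
  cf <- stats::coef(best)
  if (cf[["span"]] <= 1e-6 * max(abs(force), 1)) {
    stop("degenerate Hill fit: ceiling ~ floor, n_H unidentifiable",
         call. = FALSE)
  }
  structure(list(pca50 = cf[["pca50"]], n_h = cf[["n_h"]],
                 floor = cf[["floor"]],
                 ceiling = cf[["floor"]] + cf[["span"]],
                 rss = stats::deviance(best),
                 fitted = stats::fitted(best)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit> pCa50 = %.3f, n_H = %.3f, floor = %.4g, ceiling = %.4g, rss = %.3g\n",
    x$pca50, x$n_h, x$floor, x$ceiling, x$rss))
  invisible(x)
}

#' Normalise force to a maximal reference
#'
#' @param raw Raw force values.
#' @param f_max Maximal (reference) force; must be > 0.
#' @return `raw / f_max`.
#' @export
normalize_force <- function(raw, f_max) {
  if (!is.numeric(f_max) || length(f_max) != 1L || !is.finite(f_max) ||
      f_max <= 0) {
    stop("f_max must be a single positive number", call. = FALSE)
  }
  raw / f_max
}

#' Fit the rate of tension redevelopment (k_tr)
#'
#' Single-exponential fit `y(t) = offset + amplitude (1 - exp(-rate t))`
#' of a tension-redevelopment trace following a release-restretch
#' maneuver. Time is measured from the release (`t = 0` in traces from
#' [simulate_ktr()]); the fit starts two samples after the release to skip
#' the restretch artifact. Five deterministic rate starts bracket the
#' 63%-recovery estimate.
#'
#' @param trace A [new_trace()] with release at `t = 0` (pre-release
#'   samples, if present, carry negative times and are ignored).
#' @param t_window Optional `c(from, to)` window (s, relative to release)
#'   restricting the fitted samples.
#' @return An object of class `exp_fit`: list with `rate` (s^-1),
#'   `amplitude`, `offset`, `rss`.
#' @export
fit_ktr <- function(trace, t_window = NULL) {
  stopifnot(inherits(trace, "trace"))
  dt <- trace_dt(trace)
  keep <- trace$t >= 2 * dt - 1e-12
  if (!is.null(t_window)) {
    keep <- keep & trace$t >= t_window[1] & trace$t <= t_window[2]
  }
  tt <- trace$t[keep]; yy <- trace$y[keep]
  if (length(tt) < 20) {
    stop("fit_ktr needs >= 20 samples in the fit window", call. = FALSE)
  }
  if (stats::sd(yy) <= 1e-10 * max(abs(yy), 1)) {
    stop("fit_ktr: flat trace, no redevelopment to fit", call. = FALSE)
  }
  y0 <- yy[1]; y_end <- mean(yy[tt >= stats::quantile(tt, 0.8)])
  if (y_end <= y0) {
    stop("fit_ktr: trace does not redevelop (end level <= start level)",
         call. = FALSE)
  }
  # 63%-recovery time as the rate scale
  y63 <- y0 + 0.63 * (y_end - y0)
  i63 <- which(yy >= y63)[1]
  rate0 <- if (!is.na(i63) && tt[i63] > 0) 1 / tt[i63] else 2 / max(tt)
  df <- data.frame(t = tt, y = yy)
  fits <- lapply(rate0 * c(0.25, 0.5, 1, 2, 4), function(r0) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ offset + amplitude * (1 - exp(-rate * t)), data = df,
        start = list(offset = y0, amplitude = y_end - y0, rate = r0),
        lower = c(offset = -Inf, amplitude = 0, rate = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) {
    stop("k_tr fit failed to converge from all starts", call. = FALSE)
  }
  rss <- vapply(fits, stats::deviance, numeric(1))
  best <- fits[[which.min(rss)]]
  cf <- stats::coef(best)
  structure(list(rate = cf[["rate"]], amplitude = cf[["amplitude"]],
                 offset = cf[["offset"]], rss = stats::deviance(best)),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> rate = %.4g /s, amplitude = %.4g, offset = %.4g\n",
              x$rate, x$amplitude, x$offset))
  invisible(x)
}

#' ATPase rate from an NADH absorbance trace with ADP calibrations
#'
#' ATP consumption is read out as the NADH 340 nm absorbance decline;
#' injections of known ADP amounts produce calibration steps. The step for
#' each injection is `median(A over 1 s after) - median(A over 1 s
#' before)`; the calibration factor is the mean absorbance change per mole
#' (steps must be negative), and the rate is the negated baseline slope
#' divided by that factor. The standard injection, 50 nl of 10 mM ADP, is
#' 5e-10 mol.
#'
#' @param absorbance A [new_trace()] of 340 nm absorbance (AU).
#' @param injections data.frame with columns `time` (s) and `moles`
#'   (mol ADP), one row per injection.
#' @param calibration Optional precomputed calibration factor (AU per
#'   mol); when supplied the injection steps are not measured.
#' @param step_window Half-window (s) for the before/after step medians.
#' @return ATPase rate (mol/s), with the calibration factor as attribute
#'   `calibration`.
#' @export
atpase_rate <- function(absorbance, injections, calibration = NULL,
                        step_window = 1) {
  stopifnot(inherits(absorbance, "trace"))
  tt <- absorbance$t; yy <- absorbance$y
  if (is.null(calibration)) {
    stopifnot(is.data.frame(injections), nrow(injections) >= 1,
              all(c("time", "moles") %in% names(injections)))
    steps <- vapply(seq_len(nrow(injections)), function(i) {
      t0 <- injections$time[i]
      before <- yy[tt >= t0 - step_window & tt < t0]
      after <- yy[tt > t0 & tt <= t0 + step_window]
      if (!length(before) || !length(after)) {
        stop("injection at t = ", t0,
             " s lacks samples within the step window", call. = FALSE)
      }
      stats::median(after) - stats::median(before)
    }, numeric(1))
    if (any(steps >= 0)) {
      stop("calibration error: injection step(s) not negative (",
           paste(signif(steps, 3), collapse = ", "), " AU)", call. = FALSE)
    }
    calibration <- mean(-steps / injections$moles)  # AU per mol
  }
  if (!is.finite(calibration) || calibration <= 0) {
    stop("calibration factor must be positive", call. = FALSE)
  }
  base <- if (is.data.frame(injections) && nrow(injections) >= 1) {
    tt < min(injections$time) - step_window
  } else rep(TRUE, length(tt))
  if (sum(base) < 2) {
    stop("no baseline segment before the first injection", call. = FALSE)
  }
  slope <- stats::coef(stats::lm(yy[base] ~ tt[base]))[[2]]
  structure(-slope / calibration, calibration = calibration)
}

#' Tension cost: linear fit of ATPase versus force
#'
#' Ordinary least squares of ATPase activity against isometric force; the
#' slope is the tension cost (ATP consumed per unit force).
#'
#' @param force Force values (>= 3).
#' @param atpase ATPase values, same length.
#' @return List with `slope`, `intercept` and the underlying `lm` fit.
#' @export
tension_cost <- function(force, atpase) {
  stopifnot(is.numeric(force), is.numeric(atpase),
            length(force) == length(atpase))
  if (length(force) < 3) {
    stop("tension_cost needs >= 3 points", call. = FALSE)
  }
  if (stats::var(force) == 0) {
    stop("tension_cost: force has zero variance", call. = FALSE)
  }
  fit <- stats::lm(atpase ~ force)
  cf <- stats::coef(fit)
  list(slope = cf[[2]], intercept = cf[[1]], fit = fit)
}

#' Fiber integrity filter (80% rule)
#'
#' A fiber passes quality control when the maximal tension measured after
#' the experiment is at least 80% of the pre-experiment maximal tension
#' (boundary inclusive).
#'
#' @param max_tension_pre Pre-experiment maximal tension(s); must be > 0.
#' @param max_tension_post Post-experiment maximal tension(s).
#' @param threshold Retention threshold (default 0.80).
#' @return Logical vector: `TRUE` where the fiber is retained.
#' @examples
#' qc_fiber(100, c(85, 80, 79.9))  # TRUE TRUE FALSE
#' @export
qc_fiber <- function(max_tension_pre, max_tension_post, threshold = 0.80) {
  stopifnot(is.numeric(max_tension_pre), is.numeric(max_tension_post))
  if (any(!is.finite(max_tension_pre)) || any(max_tension_pre <= 0)) {
    stop("pre-experiment maximal tension must be positive", call. = FALSE)
  }
  max_tension_post / max_tension_pre >= threshold
}
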