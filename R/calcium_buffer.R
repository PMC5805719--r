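#' Specify an EGTA-buffered calcium solution
#'
#' Describes the total composition of a Ca2+/EGTA solution by its total
#' calcium, total EGTA and the apparent Ca-EGTA dissociation constant at the
#' working pH and ionic strength. The binding model is a single 1:1
#' Ca:EGTA equilibrium with one apparent Kd; no Mg2+/ATP competition or
#' multi-ligand speciation is attempted (see the methods vignette).
#'
#' @param total_ca Total calcium concentration (M).
#' @param total_egta Total EGTA concentration (M).
#' @param kd_app Apparent Ca-EGTA dissociation constant (M). The default,
#'   5e-8 M, makes an equimolar 20/20 mM activating solution come out at
#'   pCa 4.50, matching the standard activating-solution label.
#'
#' @return An object of class `solution_spec`.
#' @examples
#' act <- solution_spec(total_ca = 0.02, total_egta = 0.02)
#' pca_of(free_calcium(act))
#' @export
solution_spec <- function(total_ca, total_egta, kd_app = 5e-8) {
  stopifnot(is.numeric(total_ca), is.numeric(total_egta), is.numeric(kd_app),
            length(total_ca) == 1L, length(total_egta) == 1L,
            length(kd_app) == 1L)
  if (!is.finite(total_ca) || !is.finite(total_egta) || !is.finite(kd_app) ||
      total_ca < 0 || total_egta < 0 || kd_app <= 0) {
    stop("invalid solution spec: need total_ca >= 0, total_egta >= 0, ",
         "kd_app > 0", call. = FALSE)
  }
  structure(list(total_ca = total_ca, total_egta = total_egta,
                 kd_app = kd_app),
            class = "solution_spec")
}

#' @export
print.solution_spec <- function(x, ...) {
  cat(sprintf(
    "<solution_spec> total Ca %.4g M, total EGTA %.4g M, Kd(app) %.3g M\n",
    x$total_ca, x$total_egta, x$kd_app))
  invisible(x)
}

#' Free calcium concentration of an EGTA-buffered solution
#'
#' Solves the 1:1 binding equilibrium
#' \deqn{free + E_t \cdot free / (free + K_d) = Ca_t}
#' for the free Ca2+ concentration by bracketed bisection on
#' `[0, total_ca]`, refined to an absolute tolerance of 1e-12 M. The
#' closed-form quadratic root exists for this single-ligand model; bisection
#' is used so the solver extends unchanged to multi-ligand variants.
#'
#' @param sol A [solution_spec()].
#' @param tol Absolute solver tolerance (M).
#' @return Free Ca2+ concentration (M), in `[0, total_ca]`.
#' @examples
#' free_calcium(solution_spec(1e-5, 0))          # no chelator: 1e-5
#' free_calcium(solution_spec(0.02, 0.02))       # equimolar: ~3.16e-5
#' @export
free_calcium <- function(sol, tol = 1e-12) {
  if (!inherits(sol, "solution_spec")) {
    sol <- do.call(solution_spec, as.list(sol))
  }
  ca_t <- sol$total_ca
  if (ca_t == 0) return(0)
  if (sol$total_egta == 0) return(ca_t)
  # residual is monotone increasing in free on [0, ca_t]:
  # g(0) = -ca_t < 0, g(ca_t) = ca_t*E_t/(ca_t+Kd) >= 0
  g <- function(free) {
    free + sol$total_egta * free / (free + sol$kd_app) - ca_t
  }
  lo <- 0
  hi <- ca_t
  for (iter in seq_len(200L)) {
    mid <- (lo + hi) / 2
    if (mid <= lo || mid >= hi) break  # machine precision reached
    if (g(mid) > 0) hi <- mid else lo <- mid
    # refine past the absolute tolerance until the bracket is also
    # relatively tight, so micromolar and nanomolar roots are equally exact
    if ((hi - lo) <= tol && lo > 0 && (hi - lo) <= 1e-12 * lo) break
  }
  (lo + hi) / 2
}

#' Convert free calcium concentration to pCa
#'
#' `pCa = -log10([Ca2+])`. Zero free calcium maps to a finite cap
#' (default 12.0) so that relaxed-solution labels stay plot- and
#' fit-friendly.
#'
#' @param free_ca Free Ca2+ concentration (M); scalar or vector.
#' @param cap pCa value returned for zero free calcium.
#' @return pCa (dimensionless), capped at `cap`.
#' @export
pca_of <- function(free_ca, cap = 12) {
  stopifnot(is.numeric(free_ca))
  if (any(!is.finite(free_ca)) || any(free_ca < 0)) {
    stop("free_ca must be finite and >= 0", call. = FALSE)
  }
  out <- ifelse(free_ca == 0, cap, -log10(free_ca))
  pmin(out, cap)
}

#' pCa of an activating/relaxing mixing series
#'
#' Models the titration used to set intermediate calcium levels: the
#' activating and relaxing stocks are combined at each volume fraction, the
#' totals mix linearly, and the free calcium of each mixture is solved with
#' [free_calcium()]. A decreasing fraction of activating solution yields a
#' non-decreasing pCa series.
#'
#' @param activating,relaxing [solution_spec()] objects sharing `kd_app`.
#' @param volume_fractions Volume fractions of activating solution, each in
#'   `[0, 1]`.
#' @param cap pCa cap passed to [pca_of()].
#' @return Numeric vector of pCa values, one per fraction.
#' @examples
#' act <- solution_spec(0.02, 0.02)
#' rel <- solution_spec(0, 0.02)
#' mixing_series(act, rel, c(1, 0.5, 0))
#' @export
mixing_series <- function(activating, relaxing, volume_fractions, cap = 12) {
  stopifnot(inherits(activating, "solution_spec"),
            inherits(relaxing, "solution_spec"))
  if (!isTRUE(all.equal(activating$kd_app, relaxing$kd_app))) {
    stop("activating and relaxing solutions must share kd_app",
         call. = FALSE)
  }
  if (!is.numeric(volume_fractions) ||
      any(!is.finite(volume_fractions)) ||
      any(volume_fractions < 0 | volume_fractions > 1)) {
    stop("volume_fractions must lie in [0, 1]", call. = FALSE)
  }
  vapply(volume_fractions, function(f) {
    mix <- solution_spec(
      total_ca   = f * activating$total_ca + (1 - f) * relaxing$total_ca,
      total_egta = f * activating$total_egta + (1 - f) * relaxing$total_egta,
      kd_app     = activating$kd_app)
    pca_of(free_calcium(mix), cap = cap)
  }, numeric(1))
}
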