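#' Construct a filament track
#'
#' Frame-indexed 2D positions of one fluorescent thin filament from an in
#' vitro motility movie.
#'
#' @param filament_id Filament label.
#' @param x,y Positions per frame (um), >= 2 frames.
#' @param frame_rate Acquisition rate (Hz).
#' @param movie_id Optional movie label (used for per-movie SEM).
#' @return An object of class `filament_track`.
#' @export
filament_track <- function(filament_id, x, y, frame_rate, movie_id = NA) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 2L, is.numeric(frame_rate), frame_rate > 0)
  structure(list(filament_id = filament_id, movie_id = movie_id,
                 x = x, y = y, frame_rate = frame_rate),
            class = "filament_track")
}

#' Down-sample a track to a lower frame rate
#'
#' Keeps every `frame_rate / target_rate`-th frame starting at frame 0,
#' mirroring the 10 to 2 frame/s down-sampling applied to motility movies
#' before tracking.
#'
#' @param track A [filament_track()].
#' @param target_rate Target frame rate (Hz); `frame_rate` must be an
#'   integer multiple.
#' @return The down-sampled [filament_track()].
#' @export
downsample_track <- function(track, target_rate) {
  stopifnot(inherits(track, "filament_track"), target_rate > 0)
  ratio <- track$frame_rate / target_rate
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("frame_rate (", track$frame_rate, " Hz) is not an integer ",
         "multiple of target_rate (", target_rate, " Hz)", call. = FALSE)
  }
  ratio <- as.integer(round(ratio))
  idx <- seq(1L, length(track$x), by = ratio)
  filament_track(track$filament_id, track$x[idx], track$y[idx],
                 frame_rate = target_rate, movie_id = track$movie_id)
}

#' Per-filament sliding velocity
#'
#' Mean frame-to-frame path length divided by the frame interval.
#'
#' @param track A [filament_track()].
#' @return Velocity (um/s).
#' @export
track_velocity <- function(track) {
  stopifnot(inherits(track, "filament_track"))
  steps <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  mean(steps) * track$frame_rate
}

#' Classify a track as mobile or immobile
#'
#' A filament is mobile when its velocity reaches `v_min` (inclusive) and
#' its path is processive: net displacement / total path length >=
#' `straightness_min`. The straightness condition separates localisation
#' jitter, which walks nowhere, from directed sliding.
#'
#' @param track A [filament_track()].
#' @param v_min Minimum velocity (um/s).
#' @param straightness_min Minimum net-to-path displacement ratio.
#' @return `TRUE` if mobile.
#' @export
classify_mobile <- function(track, v_min = 0.3, straightness_min = 0.5) {
  stopifnot(inherits(track, "filament_track"))
  v <- track_velocity(track)
  if (v < v_min) return(FALSE)
  n <- length(track$x)
  path <- sum(sqrt(diff(track$x)^2 + diff(track$y)^2))
  if (path == 0) return(FALSE)
  net <- sqrt((track$x[n] - track$x[1])^2 + (track$y[n] - track$y[1])^2)
  net / path >= straightness_min
}

#' Motility statistic: mean velocity x fraction moving
#'
#' The thin-filament activation readout of the motility assay: the mean
#' sliding velocity of mobile filaments multiplied by the fraction of
#' filaments that move. The SEM is computed across per-movie products when
#' movie labels are present (matching triplicate independent experiments);
#' otherwise from the per-filament velocity spread scaled by the mobile
#' fraction.
#'
#' @param tracks List of [filament_track()] objects (>= 1).
#' @param v_min,straightness_min Mobility criterion, see
#'   [classify_mobile()].
#' @return An object of class `motility_stat`: list with `mean_velocity`
#'   (over mobile filaments; 0 if none), `fraction_moving`, `product`,
#'   `sem`, `n_filaments`.
#' @export
motility_statistic <- function(tracks, v_min = 0.3, straightness_min = 0.5) {
  if (!length(tracks)) stop("no tracks supplied", call. = FALSE)
  stopifnot(all(vapply(tracks, inherits, logical(1), "filament_track")))
  mobile <- vapply(tracks, classify_mobile, logical(1),
                   v_min = v_min, straightness_min = straightness_min)
  vel <- vapply(tracks, track_velocity, numeric(1))
  n <- length(tracks)
  frac <- mean(mobile)
  mv <- if (any(mobile)) mean(vel[mobile]) else 0
  movies <- vapply(tracks, function(tr) as.character(tr$movie_id),
                   character(1))
  has_movies <- !any(is.na(movies)) && length(unique(movies)) > 1
  sem <- if (has_movies) {
    per_movie <- vapply(unique(movies), function(m) {
      sel <- movies == m
      fm <- mean(mobile[sel])
      vm <- if (any(mobile[sel])) mean(vel[sel][mobile[sel]]) else 0
      fm * vm
    }, numeric(1))
    stats::sd(per_movie) / sqrt(length(per_movie))
  } else if (sum(mobile) > 1) {
    frac * stats::sd(vel[mobile]) / sqrt(sum(mobile))
  } else {
    NA_real_
  }
  structure(list(mean_velocity = mv, fraction_moving = frac,
                 product = mv * frac, sem = sem, n_filaments = n),
            class = "motility_stat")
}

#' @export
print.motility_stat <- function(x, ...) {
  cat(sprintf(
    "<motility_stat> n = %d, fraction moving = %.3f, mean velocity = %.3f um/s, product = %.3f +/- %.3f um/s\n",
    x$n_filaments, x$fraction_moving, x$mean_velocity, x$product,
    ifelse(is.na(x$sem), NA, x$sem)))
  invisible(x)
}

#' Sigmoidal dose-response fit of the motility product versus pCa
#'
#' Applies the same 4-parameter logistic fitter as [fit_hill()] to the
#' per-condition motility products, yielding the pCa50 of thin-filament
#' activation in the motility assay.
#'
#' @param stats_by_pca data.frame with columns `pca` and `product`
#'   (>= 4 pCa levels).
#' @return A `hill_fit`, see [fit_hill()].
#' @export
dose_response <- function(stats_by_pca) {
  stopifnot(is.data.frame(stats_by_pca),
            all(c("pca", "product") %in% names(stats_by_pca)))
  fit_hill(stats_by_pca$pca, stats_by_pca$product)
}

#' Convert a tracks data.frame to a list of filament tracks
#'
#' The tabular schema has one row per filament per frame with columns
#' `movie_id`, `filament_id`, `frame`, `t`, `x_um`, `y_um`.
#'
#' @param df Tracks data.frame.
#' @return List of [filament_track()] objects.
#' @export
tracks_from_df <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("movie_id", "filament_id", "frame", "t", "x_um", "y_um")
                %in% names(df)))
  key <- interaction(df$movie_id, df$filament_id, drop = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$frame), ]
    fr <- 1 / stats::median(diff(d$t))
    filament_track(d$filament_id[1], d$x_um, d$y_um,
                   frame_rate = fr, movie_id = d$movie_id[1])
  })
}

#' Read / write filament tracks in the tabular CSV schema
#'
#' @param path CSV path with columns `movie_id`, `filament_id`, `frame`,
#'   `t`, `x_um`, `y_um` (comment lines prefixed `#` allowed).
#' @return `read_tracks`: the tracks data.frame. `write_tracks`: `path`,
#'   invisibly.
#' @export
read_tracks <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' @rdname read_tracks
#' @param df Tracks data.frame to write.
#' @export
write_tracks <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
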