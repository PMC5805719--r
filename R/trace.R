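#' Construct a uniform time-series trace
#'
#' Container for uniformly sampled signals: force occupancy (dimensionless),
#' calcium concentration (M), absorbance (AU) or sarcomere length (um).
#'
#' @param t Time grid (s), strictly increasing and uniform.
#' @param y Signal values, same length as `t`.
#' @param units Label for `y` (e.g. `"fraction"`, `"M"`, `"um"`, `"AU"`).
#' @param meta Optional named list of metadata (seed, dt, parameters); kept
#'   in the `meta` attribute and written as `#` header lines by
#'   [write_trace()].
#' @return An object of class `trace`: a data.frame with columns `t`, `y`.
#' @export
new_trace <- function(t, y, units = "", meta = list()) {
  stopifnot(is.numeric(t), is.numeric(y), length(t) == length(y),
            length(t) >= 2L)
  dt <- diff(t)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * max(abs(dt))) {
    stop("t must be strictly increasing and uniformly spaced", call. = FALSE)
  }
  structure(data.frame(t = t, y = y),
            units = units, dt = dt[1], meta = meta,
            class = c("trace", "data.frame"))
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %d samples, dt = %.6g s, units = '%s'\n",
              nrow(x), attr(x, "dt"), attr(x, "units")))
  invisible(x)
}

trace_dt <- function(trace) attr(trace, "dt")

#' Write a trace as two-column CSV with metadata header
#'
#' Metadata (units, dt and anything in the `meta` attribute) is written as
#' leading comment lines of the form `# key: value`, followed by a `t,y`
#' CSV body.
#'
#' @param trace A [new_trace()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "trace"))
  meta <- c(list(units = attr(trace, "units"), dt = attr(trace, "dt")),
            attr(trace, "meta"))
  hdr <- sprintf("# %s: %s", names(meta),
                 vapply(meta, function(v) paste(format(v), collapse = " "),
                        character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(trace)[, c("t", "y")], con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' @param path File path of a `t,y` CSV with optional `# key: value` header
#'   lines.
#' @return A [new_trace()] object with the parsed metadata in `meta`.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- list()
  for (l in lines[is_meta]) {
    kv <- sub("^#\\s*", "", l)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num)) num else val
  }
  body <- utils::read.csv(text = paste(lines[!is_meta], collapse = "\n"))
  units <- if (!is.null(meta$units)) as.character(meta$units) else ""
  meta$units <- NULL
  meta$dt <- NULL
  new_trace(body$t, body$y, units = units, meta = meta)
}
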