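#' Single cell trajectory
#'
#' Builds one trajectory from time stamps and coordinates. Times are in hours,
#' coordinates in micrometres. Times must be strictly increasing and every
#' coordinate finite.
#'
#' @param id character label for the track.
#' @param times numeric vector of observation times (hours), strictly
#'   increasing.
#' @param positions numeric matrix with one row per time point and 2 or 3
#'   coordinate columns (micrometres).
#' @return An object of class `"track"`: a list with elements `id`, `times`
#'   and `positions`.
#' @seealso [track_set()]
#' @export
track <- function(id, times, positions) {
  positions <- as.matrix(positions)
  if (!is.numeric(times) || !is.numeric(positions))
    stop("times and positions must be numeric")
  if (nrow(positions) != length(times))
    stop(sprintf("track '%s': positions (%d rows) and times (%d) differ in length",
                 id, nrow(positions), length(times)))
  if (!all(is.finite(times)) || !all(is.finite(positions)))
    stop(sprintf("track '%s': non-finite times or coordinates", id))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop(sprintf("track '%s': times are not strictly increasing", id))
  if (!ncol(positions) %in% c(2L, 3L))
    stop(sprintf("track '%s': positions must have 2 or 3 columns", id))
  structure(list(id = as.character(id), times = as.numeric(times),
                 positions = unname(positions)),
            class = "track")
}

#' Number of samples in a track
#' @param x a `track`.
#' @param ... ignored.
#' @export
length.track <- function(x) length(x$times)

#' Total path length of a track
#'
#' Sum of the Euclidean magnitudes of all consecutive steps, in micrometres.
#'
#' @param tr a `track`.
#' @return numeric scalar (micrometres).
#' @export
path_length <- function(tr) {
  if (length(tr$times) < 2) return(0)
  sum(sqrt(rowSums(diff(tr$positions)^2)))
}

#' Collection of trajectories with a common sampling interval
#'
#' A `track_set` holds the tracks that all migration statistics operate on.
#' Every track's time steps must be integer multiples of the nominal sampling
#' interval `dt` (within 1e-6 h), and all tracks share one dimensionality.
#'
#' Tracks containing acquisition gaps (consecutive steps longer than
#' `gap_factor * dt`) are split into separate tracks at each gap rather than
#' interpolated, so no positions are fabricated; split parts get suffixes
#' `".1"`, `".2"`, ... Parts with fewer than 2 samples are dropped.
#'
#' @param tracks list of [track()] objects.
#' @param dt nominal sampling interval in hours. If `NULL`, inferred as the
#'   modal inter-sample interval across all tracks.
#' @param split_gaps logical; split tracks at sampling gaps (default `TRUE`).
#' @param gap_factor steps longer than `gap_factor * dt` count as gaps.
#' @return An object of class `"track_set"`: list with elements `tracks`,
#'   `dt` (hours) and `dim` (2 or 3).
#' @export
track_set <- function(tracks, dt = NULL, split_gaps = TRUE, gap_factor = 1.5) {
  stopifnot(is.list(tracks))
  tracks <- lapply(tracks, function(tr) {
    if (!inherits(tr, "track")) tr <- do.call(track, tr)
    tr
  })
  dims <- vapply(tracks, function(tr) ncol(tr$positions), integer(1))
  if (length(unique(dims)) > 1)
    stop("all tracks must share one dimensionality (2D or 3D)")
  dim <- if (length(dims)) dims[[1]] else 2L

  if (is.null(dt)) {
    steps <- unlist(lapply(tracks, function(tr) diff(tr$times)))
    if (!length(steps)) stop("cannot infer dt from tracks without steps")
    tab <- table(signif(steps, 9))
    dt <- as.numeric(names(tab)[which.max(tab)])
  }
  if (!is.finite(dt) || dt <= 0) stop("dt must be a positive number of hours")

  if (split_gaps && length(tracks)) {
    tracks <- unlist(lapply(tracks, split_track_at_gaps,
                            dt = dt, gap_factor = gap_factor),
                     recursive = FALSE)
  }

  for (tr in tracks) {
    k <- diff(tr$times) / dt
    if (any(abs(k - round(k)) > 1e-6))
      stop(sprintf("track '%s': time steps are not integer multiples of dt = %g h",
                   tr$id, dt))
  }
  structure(list(tracks = tracks, dt = dt, dim = as.integer(dim)),
            class = "track_set")
}

split_track_at_gaps <- function(tr, dt, gap_factor) {
  steps <- diff(tr$times)
  cuts <- which(steps > gap_factor * dt)
  if (!length(cuts)) return(list(tr))
  bounds <- c(0L, cuts, length(tr$times))
  parts <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    idx <- (bounds[i] + 1L):bounds[i + 1L]
    if (length(idx) < 2L) next
    parts[[length(parts) + 1L]] <-
      track(paste0(tr$id, ".", length(parts) + 1L),
            tr$times[idx], tr$positions[idx, , drop = FALSE])
  }
  parts
}

#' @export
length.track_set <- function(x) length(x$tracks)

#' @export
print.track_set <- function(x, ...) {
  n <- length(x$tracks)
  ns <- if (n) vapply(x$tracks, function(tr) length(tr$times), integer(1)) else 0L
  cat(sprintf("<track_set> %d track%s, %dD, dt = %g h, %d-%d samples/track\n",
              n, if (n == 1) "" else "s", x$dim, x$dt,
              if (n) min(ns) else 0L, if (n) max(ns) else 0L))
  invisible(x)
}

#' Convert a track set to a long data frame
#'
#' @param x a `track_set`.
#' @param row.names,optional,... ignored (standard generic arguments).
#' @return data frame with columns `track_id`, `t_h`, `x_um`, `y_um` and,
#'   for 3D sets, `z_um`.
#' @export
as.data.frame.track_set <- function(x, row.names = NULL, optional = FALSE, ...) {
  coord_names <- c("x_um", "y_um", "z_um")[seq_len(x$dim)]
  if (!length(x$tracks)) {
    out <- c(list(track_id = character(), t_h = numeric()),
             stats::setNames(rep(list(numeric()), x$dim), coord_names))
    return(as.data.frame(out, stringsAsFactors = FALSE))
  }
  parts <- lapply(x$tracks, function(tr) {
    d <- data.frame(track_id = tr$id, t_h = tr$times, stringsAsFactors = FALSE)
    for (j in seq_len(ncol(tr$positions))) d[[coord_names[j]]] <- tr$positions[, j]
    d
  })
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}

#' Read trajectories from delimited text
#'
#' One row per observation. Rows are grouped by track id and sorted by time;
#' the nominal sampling interval is inferred as the modal time difference.
#' Duplicated times within a track raise a validation error naming the track.
#'
#' @param path file to read.
#' @param sep field delimiter (default comma).
#' @param columns named character vector mapping the roles `id`, `time` and
#'   coordinates to column names in the file. Default
#'   `c(id = "track_id", time = "t_h", x = "x_um", y = "y_um", z = "z_um")`;
#'   the `z` column is optional in the file (its absence gives a 2D set).
#' @param ... further arguments passed to [track_set()] (e.g. `split_gaps`).
#' @return a [track_set()].
#' @export
read_tracks <- function(path, sep = ",",
                        columns = c(id = "track_id", time = "t_h",
                                    x = "x_um", y = "y_um", z = "z_um"),
                        ...) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- columns[c("id", "time", "x", "y")]
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(sprintf("track file format error: missing column(s) %s",
                 paste(sQuote(missing_cols), collapse = ", ")))
  has_z <- !is.na(columns["z"]) && columns[["z"]] %in% names(df)
  coord_cols <- c(columns[["x"]], columns[["y"]], if (has_z) columns[["z"]])

  tracks <- lapply(split(df, factor(df[[columns[["id"]]]],
                                    levels = unique(df[[columns[["id"]]]]))),
                   function(g) {
    g <- g[order(g[[columns[["time"]]]]), , drop = FALSE]
    tm <- g[[columns[["time"]]]]
    if (anyDuplicated(tm))
      stop(sprintf("track '%s': duplicated or non-increasing times",
                   g[[columns[["id"]]]][1]))
    track(g[[columns[["id"]]]][1], tm,
          as.matrix(g[, coord_cols, drop = FALSE]))
  })
  track_set(unname(tracks), ...)
}

#' Write trajectories as delimited text
#'
#' Inverse of [read_tracks()]: the written file round-trips coordinates and
#' ids exactly (to full double precision). An empty set writes a header-only
#' file.
#'
#' @param ts a `track_set`.
#' @param path output file.
#' @param sep field delimiter.
#' @export
write_tracks <- function(ts, path, sep = ",") {
  stopifnot(inherits(ts, "track_set"))
  df <- as.data.frame(ts)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove short tracks
#'
#' Drops every track whose total path length (sum of step magnitudes at the
#' native sampling interval) is below `min_path_length`; the conventional
#' artifact-motion filter is 30 micrometres. Order is preserved and the
#' operation is idempotent.
#'
#' @param ts a `track_set`.
#' @param min_path_length threshold in micrometres (default 30).
#' @return filtered `track_set`.
#' @export
filter_short_tracks <- function(ts, min_path_length = 30) {
  stopifnot(inherits(ts, "track_set"))
  if (!is.finite(min_path_length) || min_path_length < 0)
    stop("min_path_length must be non-negative")
  keep <- vapply(ts$tracks, function(tr) path_length(tr) >= min_path_length,
                 logical(1))
  out <- ts
  out$tracks <- ts$tracks[keep]
  out
}

#' Project 3D tracks onto the xy-plane
#'
#' Drops the third coordinate. A 2D input is returned unchanged with a
#' warning.
#'
#' @param ts a `track_set`.
#' @return a 2D `track_set` with unchanged times.
#' @export
project_to_2d <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  if (ts$dim == 2L) {
    warning("track set is already 2D; returning unchanged")
    return(ts)
  }
  out <- ts
  out$dim <- 2L
  out$tracks <- lapply(ts$tracks, function(tr) {
    tr$positions <- tr$positions[, 1:2, drop = FALSE]
    tr
  })
  out
}

#' Discard samples before a start time
#'
#' Keeps samples with time >= `t_start`; tracks left with fewer than 3
#' samples (too few for two velocity vectors) are dropped. Used to gate the
#' analysis to the time-invariant migration regime (30 h after spheroid
#' embedding in the motivating assays).
#'
#' @param ts a `track_set`.
#' @param t_start start time in hours (>= 0).
#' @return truncated `track_set` (empty, with a warning, if `t_start` is
#'   beyond all data).
#' @export
truncate_tracks <- function(ts, t_start) {
  stopifnot(inherits(ts, "track_set"))
  if (!is.finite(t_start) || t_start < 0) stop("t_start must be >= 0")
  out <- ts
  kept <- lapply(ts$tracks, function(tr) {
    idx <- which(tr$times >= t_start)
    if (length(idx) < 3L) return(NULL)
    track(tr$id, tr$times[idx], tr$positions[idx, , drop = FALSE])
  })
  out$tracks <- kept[!vapply(kept, is.null, logical(1))]
  if (!length(out$tracks))
    warning(sprintf("no track has >= 3 samples at t >= %g h; empty track set",
                    t_start))
  out
}

#' Population step speed versus time
#'
#' Bins every step of every track by the time of its midpoint into windows of
#' width `window` and reports the mean step speed |dr|/dt per window. Used to
#' verify that motility is time-invariant before applying the random-walk
#' model.
#'
#' @param ts a `track_set`.
#' @param window window width in hours (>= `dt`).
#' @return data frame with columns `time` (window centre, hours), `speed`
#'   (mean step speed, micrometres/hour) and `n_steps`; windows without steps
#'   are omitted.
#' @export
speed_vs_time <- function(ts, window) {
  stopifnot(inherits(ts, "track_set"))
  if (!is.finite(window) || window < ts$dt)
    stop("window must be at least the sampling interval dt")
  mids <- unlist(lapply(ts$tracks, function(tr)
    (tr$times[-length(tr$times)] + tr$times[-1]) / 2))
  spd <- unlist(lapply(ts$tracks, function(tr) {
    dr <- sqrt(rowSums(diff(tr$positions)^2))
    dr / diff(tr$times)
  }))
  if (!length(mids))
    return(data.frame(time = numeric(), speed = numeric(), n_steps = integer()))
  t0 <- min(vapply(ts$tracks, function(tr) tr$times[1], numeric(1)))
  bin <- floor((mids - t0) / window)
  agg <- tapply(spd, bin, mean)
  cnt <- tapply(spd, bin, length)
  data.frame(time = t0 + (as.numeric(names(agg)) + 0.5) * window,
             speed = as.numeric(agg),
             n_steps = as.integer(cnt), row.names = NULL)
}
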