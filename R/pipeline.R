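#' End-to-end trajectory analysis pipeline
#'
#' Chains the preprocessing and APRW stages: read (or accept) a track set,
#' remove short tracks, project to 2D, gate to the time-invariant regime,
#' then compute the population MSD, its power-law exponent, the angular
#' displacement distribution and the per-cell APRW fits with population
#' summary. Counts are logged at every stage so filtering is auditable.
#'
#' Defaults follow the conventions of the motivating spheroid assays: a
#' 30-micrometre minimum path length and a 30-h start gate.
#'
#' @param input a [track_set()] or a file path readable by [read_tracks()].
#' @param min_path_length track filter threshold, micrometres.
#' @param t_start gate start, hours (set 0 to keep everything).
#' @param alpha_lag_range lag window (hours) for the MSD exponent fit;
#'   `NULL` uses the middle of the available lags.
#' @param angular_lag lag (hours) for the angular displacement distribution;
#'   defaults to the sampling interval.
#' @param out_json optional path; when given, a machine-readable summary is
#'   written there as JSON.
#' @param verbose print stage-by-stage counts.
#' @param ... passed to [aprw()].
#' @return list with `aprw` (the fitted model), `population_msd`, `alpha`,
#'   `angular`, `counts` (tracks per stage) and `config` (the parameters
#'   used).
#' @export
run_tracks_pipeline <- function(input, min_path_length = 30, t_start = 30,
                                alpha_lag_range = NULL, angular_lag = NULL,
                                out_json = NULL, verbose = FALSE, ...) {
  ts <- if (inherits(input, "track_set")) input else read_tracks(input)
  counts <- c(input = length(ts))
  ts <- filter_short_tracks(ts, min_path_length)
  counts["after_length_filter"] <- length(ts)
  if (ts$dim == 3L) ts <- project_to_2d(ts)
  if (t_start > 0) ts <- truncate_tracks(ts, t_start)
  counts["after_time_gate"] <- length(ts)
  if (!length(ts$tracks)) stop("no tracks left after filtering")
  if (verbose)
    message(paste(sprintf("%s: %d", names(counts), counts), collapse = "; "))

  pm <- population_msd(ts)
  if (is.null(alpha_lag_range)) {
    lr <- range(pm$lags)
    alpha_lag_range <- c(lr[1] + 0.1 * diff(lr), lr[1] + 0.6 * diff(lr))
  }
  af <- fit_alpha(pm, alpha_lag_range)
  ang <- angular_displacements(ts, lag = angular_lag %||% ts$dt)
  model <- aprw(ts, ...)

  config <- list(min_path_length = min_path_length, t_start = t_start,
                 alpha_lag_range = alpha_lag_range,
                 angular_lag = angular_lag %||% ts$dt, dt = ts$dt)
  out <- list(aprw = model, population_msd = pm, alpha = af, angular = ang,
              counts = counts, config = config)
  if (!is.null(out_json)) {
    s <- model$summary
    doc <- list(config = config, counts = as.list(counts),
                alpha = af$alpha,
                population = list(S_p = s$S_p, P_p = s$P_p, S_np = s$S_np,
                                  P_np = s$P_np, sigma2 = s$sigma2,
                                  D_p = s$D_p, D_np = s$D_np, D_t = s$D_t,
                                  phi = s$phi,
                                  phi_ratio_of_means = s$phi_ratio_of_means,
                                  n_cells = s$n_converged,
                                  n_excluded = s$n_excluded))
    jsonlite::write_json(doc, out_json, auto_unbox = TRUE, digits = NA)
  }
  out
}

#' End-to-end microstructure pipeline
#'
#' Computes the full set of structure metrics for a labeled volume (or
#' generates one from a [volume_config()] first).
#'
#' @param input a [labeled_volume()], a [volume_config()], or a path
#'   readable by [read_labeled_volume()].
#' @param connectivity component neighbourhood (6 or 26).
#' @param out_json optional JSON output path.
#' @return a [structure_metrics()] object.
#' @export
run_volume_pipeline <- function(input, connectivity = 26, out_json = NULL) {
  vol <- if (inherits(input, "labeled_volume")) input
         else if (inherits(input, "volume_config")) generate_bicontinuous_volume(input)
         else read_labeled_volume(input)
  sm <- structure_metrics(vol, connectivity)
  if (!is.null(out_json)) {
    jsonlite::write_json(
      list(volume_fraction = as.list(sm$volume_fraction),
           connectivity_pct = as.list(sm$connectivity_pct),
           object_count = as.list(sm$object_count),
           interfacial_sa_per_volume = sm$interfacial_sa_per_volume,
           connectivity = sm$connectivity),
      out_json, auto_unbox = TRUE, digits = NA)
  }
  sm
}

#' Assemble a plain-text report from analysis results
#'
#' Deterministic human-readable rendering of trajectory and/or volume
#' results (as returned by the pipeline functions or read back from their
#' JSON outputs).
#'
#' @param results named list; recognised entries are `tracks` (output of
#'   [run_tracks_pipeline()] or its JSON document) and `volume` (a
#'   [structure_metrics()] or its JSON document).
#' @param path optional file to write the report to.
#' @return the report, invisibly, as a character vector of lines.
#' @export
make_report <- function(results, path = NULL) {
  lines <- c("== micromig analysis report ==")
  if (!is.null(results$tracks)) {
    tr <- results$tracks
    s <- if (!is.null(tr$aprw)) tr$aprw$summary else tr$population
    a <- if (!is.null(tr$alpha$alpha)) tr$alpha$alpha else tr$alpha
    lines <- c(lines, "", "[trajectories]",
               sprintf("  MSD exponent alpha: %.3f", a),
               sprintf("  S_p  = %.2f um/hr, P_p  = %.3f h", s$S_p, s$P_p),
               sprintf("  S_np = %.2f um/hr, P_np = %.3f h", s$S_np, s$P_np),
               sprintf("  D_t  = %.1f um^2/hr, phi = %.2f", s$D_t, s$phi))
  }
  if (!is.null(results$volume)) {
    v <- results$volume
    lines <- c(lines, "", "[microstructure]",
               sprintf("  volume fraction (phase0/phase1): %.3f / %.3f",
                       v$volume_fraction[[1]], v$volume_fraction[[2]]),
               sprintf("  connectivity %% (phase0/phase1): %.1f / %.1f",
                       v$connectivity_pct[[1]], v$connectivity_pct[[2]]),
               sprintf("  interfacial SA/V: %.4g 1/um",
                       v$interfacial_sa_per_volume))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
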