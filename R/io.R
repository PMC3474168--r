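#' Read an area table from CSV
#'
#' Expects columns `area_id`, `sex`, `n_examined`, `n_cases` and optionally
#' `wave`; validation errors name the offending row.
#'
#' @param path CSV path.
#' @param wave_label Optional wave label; overrides / supplies the `wave`
#'   column.
#' @return A validated area table (see [as_area_table()]).
#' @export
read_area_table <- function(path, wave_label = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  for (col in c("n_examined", "n_cases")) {
    if (col %in% names(tab)) tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  }
  if (!is.null(wave_label)) tab$wave <- as.character(wave_label)
  as_area_table(tab)
}

#' Write an area table to CSV
#' @param table An area table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_area_table <- function(table, path) {
  utils::write.csv(as_area_table(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

round_cols <- function(df, cols, digits) {
  for (co in intersect(cols, names(df))) df[[co]] <- round(df[[co]], digits)
  df
}

#' Write pipeline results to an output directory
#'
#' Emits diff-stable CSVs — risk estimates (`estimates.csv`), the per-wave
#' certainty map(s) (`certainty_map_<wave>.csv`), the change report
#' (`change_report.csv` + `transitions.csv`) — plus, when polygons are given,
#' a GeoJSON (`results.geojson`) carrying the certainty/change fields as
#' feature properties, and a `run_info.json` recording the seed and a config
#' hash. SmRRs are written with 2 decimals and probabilities with 3.
#'
#' @param outdir Output directory (created if absent).
#' @param estimates A [fit_bym()] object or estimates data frame (or `NULL`).
#' @param certainty_maps A single [build_certainty_map()] or list of them.
#' @param change_report Optional [detect_positional_changes()] result.
#' @param polygons Optional named polygon list for GeoJSON export.
#' @param seed,config Optional provenance recorded in `run_info.json`.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(outdir, estimates = NULL, certainty_maps = NULL,
                          change_report = NULL, polygons = NULL,
                          seed = NULL, config = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    written <<- c(written, p)
  }
  if (inherits(estimates, "bym")) estimates <- estimates$estimates
  if (inherits(certainty_maps, "certainty_map")) certainty_maps <- list(certainty_maps)
  area_sets <- list()
  if (!is.null(estimates)) area_sets <- c(area_sets, list(estimates$area_id))
  for (cm in certainty_maps) area_sets <- c(area_sets, list(cm$area_id))
  if (!is.null(change_report)) area_sets <- c(area_sets, list(change_report$areas$area_id))
  if (length(area_sets) > 1) {
    for (s in area_sets[-1]) {
      if (!setequal(s, area_sets[[1L]])) {
        stop_fmt("result objects cover mismatched area sets")
      }
    }
  }
  if (!is.null(estimates)) {
    est_out <- round_cols(estimates, c("smrr", "smrr_mean", "ci_low", "ci_high",
                                       "rr_raw", "expected"), 2L)
    emit(round_cols(est_out, "pr_exceed", 3L), "estimates.csv")
  }
  for (k in seq_along(certainty_maps)) {
    cm <- certainty_maps[[k]]
    wl <- attr(cm, "wave_label")
    nm <- if (nzchar(wl)) sprintf("certainty_map_%s.csv", wl)
          else sprintf("certainty_map_%d.csv", k)
    emit(round_cols(round_cols(as.data.frame(cm), "smrr", 2L), "pr_exceed", 3L), nm)
  }
  if (!is.null(change_report)) {
    ar <- change_report$areas
    ar <- round_cols(ar, c("smrr_1", "smrr_2"), 2L)
    ar <- round_cols(ar, c("pr_1", "pr_2", "pr_abs_diff"), 3L)
    emit(ar, "change_report.csv")
    emit(as.data.frame(change_report$transitions), "transitions.csv")
  }
  if (!is.null(polygons)) {
    props <- NULL
    if (!is.null(change_report)) {
      props <- change_report$areas[, c("area_id", "color_1", "color_2", "evidential")]
    } else if (length(certainty_maps)) {
      cm <- certainty_maps[[1L]]
      props <- data.frame(area_id = cm$area_id, color = as.character(cm$color),
                          pr_exceed = round(cm$pr_exceed, 3L),
                          smrr = round(cm$smrr, 2L),
                          certainty_rank = cm$certainty_rank,
                          stringsAsFactors = FALSE)
    } else if (!is.null(estimates)) {
      props <- round_cols(estimates[, c("area_id", "smrr", "pr_exceed")], "smrr", 2L)
      props <- round_cols(props, "pr_exceed", 3L)
    }
    p <- file.path(outdir, "results.geojson")
    write_geojson(polygons, p, properties = props)
    written <- c(written, p)
  }
  info <- list(seed = seed,
               config_hash = if (!is.null(config)) config_hash(config) else NULL,
               package = "arealrisk",
               version = as.character(utils::packageVersion("arealrisk")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  p <- file.path(outdir, "run_info.json")
  jsonlite::write_json(info[!vapply(info, is.null, logical(1))], p,
                       auto_unbox = TRUE, pretty = TRUE)
  written <- c(written, p)
  invisible(written)
}

# Small deterministic hash of a configuration list (provenance stamping).
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  codes <- utf8ToInt(as.character(s))
  h <- 0
  for (c0 in codes) h <- (h * 31 + c0) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Read a pipeline configuration file
#'
#' A flat YAML document; recognized keys mirror the arguments of
#' [sim_config()], [fit_bym()] (`n_iter`, `n_burnin`, `thin`, `n_chains`),
#' `threshold`, `delta` and `seed`. Unknown keys are kept as-is so callers
#' can extend the format.
#'
#' @param path YAML file path.
#' @param overrides Named list of values overriding the file's.
#' @return Named list.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop_fmt("%s: configuration must be a YAML mapping", path)
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  cfg
}

#' Run the full two-wave risk-mapping pipeline
#'
#' Composes the whole analysis: (optionally) simulate two survey waves on the
#' graph, indirectly standardize each wave, fit the BYM smoothing model per
#' wave independently, classify certainty colors and ranks, and detect
#' evidential positional changes. Identical to calling the stages manually
#' with the same seeds.
#'
#' @param graph An [adjacency_graph()].
#' @param wave1,wave2 Area tables for the two waves; if `NULL`, both are
#'   simulated from `sim` (whose `seed` drives the generator).
#' @param sim A [sim_config()] used when simulating.
#' @param threshold Certainty threshold (default 0.95).
#' @param delta Evidential-change probability shift (default 0.25).
#' @param seed Master seed for the MCMC.
#' @param wave_labels Labels for the two waves.
#' @param outdir Optional directory; when given, all artifacts are written
#'   via [write_results()].
#' @param polygons Optional polygons for GeoJSON export.
#' @param ... Further arguments passed to [fit_bym()] (chain lengths etc.).
#' @return A list of class `risk_pipeline`: `fit1`, `fit2` ([fit_bym()]
#'   objects), `map1`, `map2` (certainty maps), `changes` (change report),
#'   and `sim` (the simulation output when data were simulated).
#' @export
#' @examples
#' \donttest{
#' gg <- grid_geography(3, 3)
#' out <- run_two_wave_pipeline(gg$graph, sim = sim_config(seed = 2),
#'                              n_iter = 500, n_burnin = 200, n_chains = 1)
#' out$changes
#' }
run_two_wave_pipeline <- function(graph, wave1 = NULL, wave2 = NULL,
                                  sim = sim_config(), threshold = 0.95,
                                  delta = 0.25, seed = 1L,
                                  wave_labels = c("wave1", "wave2"),
                                  outdir = NULL, polygons = NULL, ...) {
  stopifnot(inherits(graph, "adjacency_graph"))
  sim_out <- NULL
  if (is.null(wave1) || is.null(wave2)) {
    sim_out <- simulate_two_waves(graph, sim)
    wave1 <- wave1 %||% sim_out$wave1
    wave2 <- wave2 %||% sim_out$wave2
  }
  wave1 <- as_area_table(wave1, graph)
  wave2 <- as_area_table(wave2, graph)
  fit1 <- fit_bym(area_summary(wave1), graph,
                  seed = substream_seed(seed, "fit", 1L), ...)
  fit2 <- fit_bym(area_summary(wave2), graph,
                  seed = substream_seed(seed, "fit", 2L), ...)
  map1 <- build_certainty_map(fit1, threshold, wave_label = wave_labels[[1L]])
  map2 <- build_certainty_map(fit2, threshold, wave_label = wave_labels[[2L]])
  changes <- detect_positional_changes(map1, map2, delta = delta)
  if (!is.null(outdir)) {
    write_results(outdir, estimates = fit1, certainty_maps = list(map1, map2),
                  change_report = changes, polygons = polygons, seed = seed,
                  config = list(threshold = threshold, delta = delta,
                                sim_seed = sim$seed))
  }
  structure(list(fit1 = fit1, fit2 = fit2, map1 = map1, map2 = map2,
                 changes = changes, sim = sim_out,
                 settings = list(threshold = threshold, delta = delta, seed = seed)),
            class = "risk_pipeline")
}

#' @export
print.risk_pipeline <- function(x, ...) {
  cat("Two-wave small-area risk pipeline\n")
  cat(sprintf("  wave 1 polarization ratio: %.1f\n",
              polarization_ratio(x$map1$smrr)))
  cat(sprintf("  wave 2 polarization ratio: %.1f\n",
              polarization_ratio(x$map2$smrr)))
  print(x$changes)
  invisible(x)
}
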