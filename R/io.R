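## File formats: comma-separated UTF-8 with '.' decimal and a header row;
## tab-separated accepted for files ending in .tsv. Times in seconds
## throughout; frame 0 corresponds to t = 0.

.read_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  reader <- if (grepl("\\.tsv$", path, ignore.case = TRUE))
    readr::read_tsv else readr::read_csv
  reader(path, show_col_types = FALSE, progress = FALSE)
}

.warn_extra_cols <- function(df, expected, what, path) {
  extra <- setdiff(names(df), expected)
  if (length(extra) > 0) {
    warn(sprintf("%s %s: ignoring unknown column(s) %s.",
                 what, path, paste(extra, collapse = ", ")))
  }
}

#' Read a long-format BOLD table
#'
#' Reads a CSV/TSV file with columns `roi`, `t` (seconds) and `y` and
#' validates it as a BOLD dataset: complete ROI-by-frame coverage, a uniform
#' frame grid with spacing `tr` starting at `t = 0`, no duplicated
#' `(roi, t)` rows and no missing values. Malformed files fail with a
#' message naming the offending ROI, time or spacing.
#'
#' @param path Path to the file.
#' @param tr Repetition time in seconds the frame grid must match.
#' @return A validated tibble with columns `roi`, `t`, `y`.
#' @export
read_bold <- function(path, tr) {
  df <- .read_table(path)
  .require_columns(df, c("roi", "t", "y"), sprintf("BOLD file %s", path))
  .warn_extra_cols(df, c("roi", "t", "y"), "BOLD file", path)
  bm <- .as_bold_matrix(df[, c("roi", "t", "y")], tr)
  tibble(
    roi = rep(bm$rois, each = bm$n_frames),
    t = rep(bm$frame_times, times = length(bm$rois)),
    y = as.vector(t(bm$values))
  )
}

#' Read an event-model table
#'
#' Reads a CSV/TSV file with columns `event`, `start_time`, `duration`
#' (seconds) and validates it (unique event names, positive durations).
#'
#' @param path Path to the file.
#' @return A validated event-model tibble.
#' @export
read_event_model <- function(path) {
  df <- .read_table(path)
  .require_columns(df, c("event", "start_time", "duration"),
                   sprintf("event-model file %s", path))
  .warn_extra_cols(df, c("event", "start_time", "duration"),
                   "event-model file", path)
  .as_event_model(df, path)
}

#' Read a constraint table
#'
#' Reads a CSV/TSV file with columns `event`, `start_time`, `end_time` and
#' optional `min_duration`, `max_duration` (seconds), and validates the
#' windows (`start_time < end_time`, duration bounds feasible).
#'
#' @param path Path to the file.
#' @param min_duration_floor Duration floor for events without
#'   `min_duration` (see [as_constraints()]).
#' @return A validated constraint tibble.
#' @export
read_constraints <- function(path, min_duration_floor = 1e-3) {
  df <- .read_table(path)
  .require_columns(df, c("event", "start_time", "end_time"),
                   sprintf("constraints file %s", path))
  .warn_extra_cols(df, c("event", "start_time", "end_time",
                         "min_duration", "max_duration"),
                   "constraints file", path)
  as_constraints(df, min_duration_floor)
}

#' Write evaluation or search results to a directory
#'
#' `write_results()` is a generic that persists a result object as a set of
#' plain-text files plus a machine-readable run manifest
#' (`manifest.json` with the full effective configuration, the seed, and
#' package/R versions).
#'
#' For an `event_fit`: `fit.json` (aggregates and per-ROI records),
#' `fit_by_roi.csv`, and `fit_timecourses.csv` (observed, predicted and
#' per-event contribution series for plotting).
#'
#' For an `event_search`: `search.json` (configuration, best models,
#' traces), one `best_model_<set>.csv` per constraint set, and
#' `fitness_trace.csv` (`constraint_set`, `iteration`, `fitness`).
#'
#' @param x Result object.
#' @param dir Output directory (created if needed).
#' @param ... Unused.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(x, dir, ...) UseMethod("write_results")

.write_manifest <- function(dir, config) {
  manifest <- list(
    config = config,
    package = "fmrievents",
    package_version = as.character(packageVersion("fmrievents")),
    r_version = R.version.string,
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

.hrf_config <- function(hrf) {
  list(method = hrf$method, tr = hrf$tr, f = hrf$f,
       p_boynton = hrf$p_boynton, p_spm = hrf$p_spm)
}

#' @rdname write_results
#' @export
write_results.event_fit <- function(x, dir, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  fit_json <- file.path(dir, "fit.json")
  jsonlite::write_json(
    list(aggregates = x$aggregates, by_roi = x$by_roi, model = x$model),
    fit_json, auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE
  )
  paths <- c(paths, fit_json)

  by_roi_csv <- file.path(dir, "fit_by_roi.csv")
  readr::write_csv(x$by_roi, by_roi_csv)
  paths <- c(paths, by_roi_csv)

  tc <- dplyr::left_join(
    x$timecourses,
    tidyr::pivot_wider(x$contributions, names_from = "event",
                       values_from = "value", names_prefix = "contrib_"),
    by = c("roi", "t")
  )
  tc_csv <- file.path(dir, "fit_timecourses.csv")
  readr::write_csv(tc, tc_csv)
  paths <- c(paths, tc_csv)

  paths <- c(paths, .write_manifest(dir, list(
    kind = "evaluate", tr = x$tr, hrf = .hrf_config(x$hrf),
    roi_weights = as.list(x$weights)
  )))
  invisible(paths)
}

#' @rdname write_results
#' @export
write_results.event_search <- function(x, dir, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  search_json <- file.path(dir, "search.json")
  jsonlite::write_json(
    list(
      config = .search_config(x),
      results = lapply(x$results, function(r) {
        list(set = r$set, best_fitness = r$best_fitness,
             best_model = r$best_model, constraints = r$constraints,
             trace = r$trace, population = r$population,
             population_fitness = r$population_fitness)
      })
    ),
    search_json, auto_unbox = TRUE, digits = NA, dataframe = "rows",
    pretty = TRUE
  )
  paths <- c(paths, search_json)

  for (r in x$results) {
    p <- file.path(dir, sprintf("best_model_%s.csv", r$set))
    readr::write_csv(r$best_model, p)
    paths <- c(paths, p)
  }

  trace_csv <- file.path(dir, "fitness_trace.csv")
  readr::write_csv(fitness_trace(x), trace_csv)
  paths <- c(paths, trace_csv)

  paths <- c(paths, .write_manifest(dir, c(list(kind = "search"),
                                           .search_config(x))))
  invisible(paths)
}

.search_config <- function(x) {
  cfg <- x$config
  cfg$hrf <- .hrf_config(cfg$hrf)
  cfg
}

#' Re-load a written search result
#'
#' Reads the `search.json` produced by [write_results()] for an
#' `event_search` and reconstructs the object, including the final
#' populations, so a finished run can be passed to
#' `optimize_events(resume = ...)` to continue the search.
#'
#' @param path Path to a `search.json` file, or to the directory containing
#'   it.
#' @return An `event_search` object.
#' @export
read_search_results <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "search.json")
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  js <- jsonlite::read_json(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  cfg <- js$config
  hrf <- hrf_spec(cfg$hrf$method, tr = cfg$hrf$tr, f = cfg$hrf$f,
                  p_boynton = cfg$hrf$p_boynton, p_spm = cfg$hrf$p_spm)
  results <- lapply(js$results, function(r) {
    list(
      set = r$set,
      constraints = as_tibble(r$constraints),
      best_model = as_tibble(r$best_model),
      best_fitness = r$best_fitness,
      trace = r$trace,
      population = lapply(r$population, as_tibble),
      population_fitness = r$population_fitness
    )
  })
  names(results) <- vapply(results, function(r) r$set, character(1))
  structure(
    list(results = results,
         config = list(population = cfg$population, iter = cfg$iter,
                       mutation_rate = cfg$mutation_rate,
                       elitism = cfg$elitism,
                       mutation_sd_frac = cfg$mutation_sd_frac,
                       seed = cfg$seed, tr = cfg$tr, hrf = hrf,
                       resumed = isTRUE(cfg$resumed)),
         weights = NULL),
    class = "event_search"
  )
}
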