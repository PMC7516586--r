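# Delimited-text IO for recordings and maps, and the end-to-end pipeline.
#
# Recordings travel as plain CSV with one row per sample
# (participant, session, point, time_ms, velocity | position): there is no
# entrenched interchange format for eye-tracker exports, so the schema is
# deliberately minimal and documented in the README.

#' Write / read a recording table
#'
#' @param data Recording tibble (one row per sample).
#' @param path CSV file path.
#' @return `write_recordings()` returns `path` invisibly;
#'   `read_recordings()` returns a validated recording tibble.
#' @name recordings_io
NULL

#' @rdname recordings_io
#' @export
write_recordings <- function(data, path) {
  check_recordings(data)
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname recordings_io
#' @param format `"velocity"` (default) or `"position"`; position input is
#'   converted with [differentiate_positions()] (one sample is lost per
#'   series, so supply N + 1 positions for N velocities).
#' @param expected_samples Required series length after conversion (default
#'   1024); under `strict = TRUE` series of any other length are rejected
#'   (with a message counting them), otherwise longer series are truncated
#'   and shorter ones rejected.
#' @param rate_hz Sampling rate (default 1000).
#' @param strict Reject rather than truncate (default TRUE).
#' @export
read_recordings <- function(path, format = c("velocity", "position"),
                            expected_samples = 1024L, rate_hz = 1000,
                            strict = TRUE) {
  format <- match.arg(format)
  value_col <- if (format == "velocity") "velocity" else "position"
  raw <- readr::read_csv(path, show_col_types = FALSE)
  need <- c(series_id_cols, value_col)
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop("File ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), ".", call. = FALSE)
  }
  bad_rows <- !stats::complete.cases(raw[, need]) |
    !is.finite(raw[[value_col]])
  if (any(bad_rows)) {
    message(sum(bad_rows), " malformed row(s) dropped (lines ",
            paste(utils::head(which(bad_rows) + 1L, 5L), collapse = ", "),
            if (sum(bad_rows) > 5L) ", ..." else "", ").")
    raw <- raw[!bad_rows, ]
  }
  dt_ms <- 1000 / rate_hz
  series <- raw |>
    dplyr::group_by(dplyr::across(dplyr::all_of(series_id_cols))) |>
    dplyr::group_map(function(df, key) {
      v <- df[[value_col]]
      if (format == "position") {
        v <- differentiate_positions(v, dt = 1 / rate_hz)
      }
      if (length(v) != expected_samples) {
        if (strict || length(v) < expected_samples) return(NULL)
        v <- v[seq_len(expected_samples)]
      }
      dplyr::bind_cols(key,
                       tibble::tibble(time_ms = (seq_along(v) - 1) * dt_ms,
                                      velocity = v))
    })
  rejected <- sum(purrr::map_lgl(series, is.null))
  if (rejected > 0L) {
    message(rejected, " series rejected (wrong length).")
  }
  out <- dplyr::bind_rows(series)
  if (nrow(out) == 0L) {
    stop("No valid series in ", path, ".", call. = FALSE)
  }
  out
}

#' Pipeline configuration
#'
#' Bundles every knob of the simulate - map - features - classify chain.
#' All values in effect are echoed into the run manifest, so no parameter
#' defaults silently.
#'
#' @param synth A [synth_config()] (used when no input file is given).
#' @param input_path Optional recordings CSV to analyse instead of
#'   simulating.
#' @param measures Measure parameter bundles for [build_maps()].
#' @param specs List of [feature_spec()]s to classify with.
#' @param k_grid Neighbour counts to run (study grid
#'   `c(3, 7, 15, 31, 63, 127, 255)`; default keeps `63`, the value the
#'   study settled on).
#' @param normalization `"pooled"` (min-max over the full dataset before
#'   splitting, the study's ordering) or `"fold_safe"`.
#' @param first_n_segments Rows of the final accuracy table (default 4).
#' @param nss_ms,nemr_ms,rate_hz Map geometry.
#' @param seed Seed recorded for the run.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            input_path = NULL,
                            measures = list(apen_params(), fuzen_params(),
                                            lle_params()),
                            specs = list(feature_spec(1:3)),
                            k_grid = 63L,
                            normalization = c("pooled", "fold_safe"),
                            first_n_segments = 4L,
                            nss_ms = 64, nemr_ms = 1024, rate_hz = 1000,
                            seed = 1L) {
  normalization <- match.arg(normalization)
  structure(list(synth = synth, input_path = input_path,
                 measures = measures, specs = specs,
                 k_grid = as.integer(k_grid), normalization = normalization,
                 first_n_segments = first_n_segments,
                 nss_ms = nss_ms, nemr_ms = nemr_ms, rate_hz = rate_hz,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' simulate (or read) recordings, build the three multilevel maps,
#' normalise, assemble each configured feature set, cross-validate kNN over
#' the k grid, and write every artifact plus a reproducibility manifest to
#' `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param figures Also render map / accuracy figures as PNG (default FALSE;
#'   requires a PNG device).
#' @return Invisibly, a list with `recordings`, `maps`, `avg_maps`,
#'   `reports` (list of `knn_report`), `accuracy` (tidy accuracy table) and
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir, figures = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    s <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
    timings[[name]] <<- round(as.numeric(Sys.time() - s, units = "secs"), 3)
    res
  }

  recordings <- stage("input", {
    if (!is.null(config$input_path)) {
      read_recordings(config$input_path,
                      expected_samples = config$nemr_ms * config$rate_hz / 1000,
                      rate_hz = config$rate_hz)
    } else {
      cfg <- config$synth
      cfg$seed <- config$seed
      generate_dataset(cfg)
    }
  })
  write_recordings(recordings, file.path(out_dir, "recordings.csv"))

  maps <- stage("map", build_maps(recordings, config$measures,
                                  nss_ms = config$nss_ms,
                                  nemr_ms = config$nemr_ms,
                                  rate_hz = config$rate_hz))
  maps <- stage("normalize", normalize_maps(maps))
  readr::write_csv(maps, file.path(out_dir, "maps.csv"))
  avg <- average_maps(maps)
  readr::write_csv(avg, file.path(out_dir, "maps_averaged.csv"))

  reports <- stage("classify", {
    grid <- tidyr::expand_grid(spec_i = seq_along(config$specs),
                               k = config$k_grid)
    purrr::pmap(grid, function(spec_i, k) {
      spec <- config$specs[[spec_i]]
      if (config$normalization == "fold_safe") {
        feats <- assemble_features(maps, spec, value_col = "value")
        knn_loso_cv(feats, k = k, normalization = "fold_safe")
      } else {
        feats <- assemble_features(maps, spec)
        knn_loso_cv(feats, k = k)
      }
    })
  })
  acc_long <- dplyr::bind_rows(purrr::map(reports, tidy.knn_report))
  readr::write_csv(acc_long, file.path(out_dir, "accuracy_long.csv"))
  acc_tab <- accuracy_table(reports, config$first_n_segments)
  readr::write_csv(acc_tab, file.path(out_dir, "accuracy_table.csv"))
  jsonlite::write_json(
    purrr::map(reports, function(r) {
      list(spec = r$spec, k = r$k, n_folds = r$n_folds,
           confusion = unclass(r$confusion))
    }),
    file.path(out_dir, "reports.json"), auto_unbox = TRUE)

  if (isTRUE(figures)) {
    tryCatch({
      ggplot2::ggsave(file.path(out_dir, "maps_averaged.png"),
                      autoplot.oculomap_avg(avg), width = 9, height = 5,
                      dpi = 150)
    }, error = function(e) {
      warning("Figure rendering skipped: ", conditionMessage(e),
              call. = FALSE)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("oculomap")),
    r_version = R.version.string,
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    geometry = list(nss_ms = config$nss_ms, nemr_ms = config$nemr_ms,
                    rate_hz = config$rate_hz),
    normalization = config$normalization,
    k_grid = config$k_grid,
    specs = purrr::map_chr(config$specs, "name"),
    measures = purrr::map(config$measures,
                          function(p) unclass(p[!purrr::map_lgl(p, is.null)])),
    synth = if (is.null(config$input_path)) {
      unclass(config$synth[!purrr::map_lgl(unclass(config$synth), is.null)])
    },
    input_path = config$input_path,
    n_series = nrow(dplyr::distinct(
      recordings, dplyr::across(dplyr::all_of(series_id_cols)))),
    missing_cells = sum(is.na(maps$value)),
    dropped_feature_rows = NULL,
    timings_s = timings
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(recordings = recordings, maps = maps, avg_maps = avg,
                 reports = reports, accuracy = acc_tab, manifest = manifest))
}
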