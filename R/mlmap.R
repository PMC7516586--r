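# The multilevel map: a dyadic time-scale decomposition of a measure.
#
# A 1024 ms velocity series at 1000 Hz is tiled at level 1 into 64 ms
# segments; each higher level merges two adjacent segments, up to level 5 =
# the whole series. Each map cell holds one measure (ApEn, FuzEn or LLE)
# evaluated on exactly that segment's samples. Maps live in long tibbles
# (series identity, measure, level, index, window, value) so they compose
# with dplyr.

#' Number of map levels for a given geometry
#'
#' @param nemr_ms Series duration in ms (default 1024).
#' @param nss_ms Level-1 segment length in ms (default 64).
#' @return Integer number of levels (5 at the defaults). Errors unless the
#'   duration is `nss_ms` times a power of two.
#' @export
map_levels <- function(nemr_ms = 1024, nss_ms = 64) {
  ratio <- nemr_ms / nss_ms
  l <- log2(ratio)
  if (nss_ms <= 0 || ratio < 1 || abs(l - round(l)) > 1e-9) {
    stop("Duration (", nemr_ms, " ms) must be the base segment (", nss_ms,
         " ms) times a power of two.", call. = FALSE)
  }
  as.integer(round(l)) + 1L
}

#' Segment window of a map cell
#'
#' Cells are labelled 1-based by (level, index); the window is half-open,
#' `[ (index-1)*len, index*len )` ms with `len = nss_ms * 2^(level-1)`.
#'
#' @param level Map level, 1 (finest) .. L (whole series).
#' @param index Segment index within the level; vectorised.
#' @param nss_ms,nemr_ms Map geometry (defaults 64 and 1024 ms).
#' @return A tibble with columns `level`, `index`, `start_ms`, `end_ms`,
#'   `length_ms`.
#' @export
#' @examples
#' segment_bounds(2, 2) # 128-256 ms
segment_bounds <- function(level, index, nss_ms = 64, nemr_ms = 1024) {
  L <- map_levels(nemr_ms, nss_ms)
  level <- as.integer(level); index <- as.integer(index)
  if (any(level < 1L) || any(level > L)) {
    stop("`level` must be in 1..", L, ".", call. = FALSE)
  }
  len <- nss_ms * 2^(level - 1)
  n_seg <- nemr_ms / len
  if (any(index < 1L) || any(index > n_seg)) {
    stop("`index` out of range for level ", paste(unique(level), collapse = ","),
         " (1..", paste(unique(n_seg), collapse = ","), ").", call. = FALSE)
  }
  tibble::tibble(level = level, index = index,
                 start_ms = (index - 1) * len, end_ms = index * len,
                 length_ms = len)
}

#' Class count for a feature set whose finest level is `l_x`
#'
#' The number of classes equals the number of segments at the finest level
#' entering the feature vector: `nemr_ms / (nss_ms * 2^(l_x - 1))` — 16, 8,
#' 4, 2 for levels 1-4 at the default geometry.
#'
#' @param l_x Finest map level in the feature set.
#' @param nss_ms,nemr_ms Map geometry.
#' @return Integer class count.
#' @export
class_count <- function(l_x, nss_ms = 64, nemr_ms = 1024) {
  L <- map_levels(nemr_ms, nss_ms)
  l_x <- as.integer(l_x)
  if (any(l_x < 1L) || any(l_x > L)) {
    stop("`l_x` must be in 1..", L, ".", call. = FALSE)
  }
  as.integer(nemr_ms / (nss_ms * 2^(l_x - 1)))
}

#' Measure parameter bundles
#'
#' Constructors for the per-measure parameters used by [build_maps()].
#' Entropy tolerances are coefficients on a standard deviation; with the
#' default scope `"whole_series"` the SD of the full parent series is used
#' for every cell (a segment-scope option exists for sensitivity analysis).
#' For the Lyapunov map, the embedding is selected once per series via
#' mutual information and false nearest neighbours, and falls back to the
#' fixed `(fallback_m, fallback_tau)` for segments with fewer than
#' `min_vectors` state vectors.
#'
#' @param m Pattern length / embedding dimension.
#' @param r_coef Tolerance coefficient (x SD).
#' @param r_scope `"whole_series"` or `"segment"`.
#' @param n Fuzzy-boundary gradient.
#' @param follow_steps,dt,min_sep,mode See [largest_lyapunov()].
#' @param embedding `"fnn_mi_auto"` (per-series selection) or `"fixed"`.
#' @param fixed_m,fixed_tau Embedding used when `embedding = "fixed"`.
#' @param fallback_m,fallback_tau,min_vectors Segment-level fallback.
#' @param max_lag,bins,max_m FNN/MI selection controls.
#' @return A named list of class `"oculomap_params"`.
#' @name measure_params
NULL

#' @rdname measure_params
#' @export
apen_params <- function(m = 2L, r_coef = 0.2,
                        r_scope = c("whole_series", "segment")) {
  stopifnot(m >= 1, r_coef > 0)
  structure(list(measure = "ApEn", m = as.integer(m), r_coef = r_coef,
                 r_scope = match.arg(r_scope)),
            class = "oculomap_params")
}

#' @rdname measure_params
#' @export
fuzen_params <- function(m = 2L, n = 2, r_coef = 0.075,
                         r_scope = c("whole_series", "segment")) {
  stopifnot(m >= 1, n > 0, r_coef > 0)
  structure(list(measure = "FuzEn", m = as.integer(m), n = n,
                 r_coef = r_coef, r_scope = match.arg(r_scope)),
            class = "oculomap_params")
}

#' @rdname measure_params
#' @export
lle_params <- function(follow_steps = 10L, dt = 0.001, min_sep = NULL,
                       mode = c("horizon_average", "rosenstein_slope"),
                       embedding = c("fnn_mi_auto", "fixed"),
                       fixed_m = 2L, fixed_tau = 1L,
                       fallback_m = 2L, fallback_tau = 1L,
                       min_vectors = 10L,
                       max_lag = 50L, bins = 16L, max_m = 8L) {
  structure(list(measure = "LLE", follow_steps = as.integer(follow_steps),
                 dt = dt, min_sep = min_sep, mode = match.arg(mode),
                 embedding = match.arg(embedding),
                 fixed_m = as.integer(fixed_m),
                 fixed_tau = as.integer(fixed_tau),
                 fallback_m = as.integer(fallback_m),
                 fallback_tau = as.integer(fallback_tau),
                 min_vectors = as.integer(min_vectors),
                 max_lag = as.integer(max_lag), bins = as.integer(bins),
                 max_m = as.integer(max_m)),
            class = "oculomap_params")
}

series_id_cols <- c("participant", "session", "point")

check_recordings <- function(data) {
  need <- c(series_id_cols, "time_ms", "velocity")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    stop("Recordings are missing column(s): ", paste(miss, collapse = ", "),
         ".", call. = FALSE)
  }
  invisible(data)
}

# Evaluate one measure on every cell of one series. Returns the long cell
# tibble; failed cells carry NA and the condition message in `note`.
map_one_series <- function(u, params, nss_ms, nemr_ms, rate_hz) {
  L <- map_levels(nemr_ms, nss_ms)
  cells <- dplyr::bind_rows(lapply(seq_len(L), function(l) {
    segment_bounds(l, seq_len(nemr_ms / (nss_ms * 2^(l - 1))),
                   nss_ms = nss_ms, nemr_ms = nemr_ms)
  }))
  samples_per_ms <- rate_hz / 1000

  measure <- params$measure
  if (measure %in% c("ApEn", "FuzEn")) {
    sd_whole <- series_sd(u)
    eval_cell <- function(seg) {
      s <- if (params$r_scope == "whole_series") sd_whole else series_sd(seg)
      r_abs <- params$r_coef * s
      if (measure == "ApEn") {
        approximate_entropy(seg, m = params$m, r_abs = r_abs)
      } else {
        fuzzy_entropy(seg, m = params$m, n = params$n, r_abs = r_abs)
      }
    }
  } else if (measure == "LLE") {
    if (params$embedding == "fnn_mi_auto") {
      # flagged selections (no MI minimum / no FNN plateau, i.e. noise-like
      # series) fall back to the fixed embedding rather than a junk (m, tau)
      tau <- tryCatch({
        sel <- select_lag_mi(u, max_lag = params$max_lag, bins = params$bins)
        if (isTRUE(attr(sel, "fallback"))) params$fallback_tau
        else as.integer(sel)
      }, error = function(e) params$fallback_tau)
      m <- tryCatch({
        sel <- select_dim_fnn(u, tau = tau, max_m = params$max_m)
        if (isTRUE(attr(sel, "fallback"))) params$fallback_m
        else as.integer(sel)
      }, error = function(e) params$fallback_m)
    } else {
      tau <- params$fixed_tau
      m <- params$fixed_m
    }
    eval_cell <- function(seg) {
      n <- length(seg)
      mm <- m; tt <- tau
      if (n - (mm - 1L) * tt < params$min_vectors + params$follow_steps) {
        mm <- params$fallback_m; tt <- params$fallback_tau
      }
      largest_lyapunov(seg, m = mm, tau = tt,
                       follow_steps = params$follow_steps, dt = params$dt,
                       min_sep = params$min_sep, mode = params$mode)
    }
  } else {
    stop("Unknown measure ", measure, call. = FALSE)
  }

  out <- purrr::pmap(cells, function(level, index, start_ms, end_ms, length_ms) {
    i0 <- start_ms * samples_per_ms + 1
    i1 <- end_ms * samples_per_ms
    seg <- u[i0:i1]
    tryCatch(list(value = eval_cell(seg), note = NA_character_),
             error = function(e) list(value = NA_real_,
                                      note = conditionMessage(e)))
  })
  cells$measure <- measure
  cells$value <- purrr::map_dbl(out, "value")
  cells$note <- purrr::map_chr(out, "note")
  cells
}

#' Build multilevel maps for every series in a recording table
#'
#' For each (participant, session, point) series and each requested measure,
#' evaluates the measure on every dyadic segment of the multilevel map.
#' Entropy tolerances use the whole-series SD by default; the Lyapunov
#' embedding is selected once per series (MI lag, FNN dimension) and reused
#' for every segment, with a fixed fallback for segments too short to embed.
#' Cells whose measure evaluation fails are kept with `value = NA` and the
#' reason in `note` — never silently zero.
#'
#' @param data Recording tibble: columns `participant`, `session`, `point`,
#'   `time_ms`, `velocity`, e.g. from [generate_dataset()] or
#'   [read_recordings()].
#' @param measures List of parameter bundles ([apen_params()],
#'   [fuzen_params()], [lle_params()]); defaults to all three at the
#'   standard settings.
#' @param nss_ms,nemr_ms Map geometry (defaults 64 and 1024 ms).
#' @param rate_hz Sampling rate (default 1000).
#' @return A long tibble with one row per series x measure x cell:
#'   identity columns, `measure`, `level`, `index`, `start_ms`, `end_ms`,
#'   `length_ms`, `value`, `note`.
#' @export
build_maps <- function(data,
                       measures = list(apen_params(), fuzen_params(),
                                       lle_params()),
                       nss_ms = 64, nemr_ms = 1024, rate_hz = 1000) {
  check_recordings(data)
  if (inherits(measures, "oculomap_params")) measures <- list(measures)
  n_expect <- nemr_ms * rate_hz / 1000
  data <- dplyr::arrange(data, .data$participant, .data$session, .data$point,
                         .data$time_ms)
  series <- dplyr::group_split(data,
                               dplyr::across(dplyr::all_of(series_id_cols)))
  res <- purrr::map(series, function(s) {
    if (nrow(s) != n_expect) {
      stop("Series (", s$participant[1], ", ", s$session[1], ", ",
           s$point[1], ") has ", nrow(s), " samples; expected ", n_expect,
           ".", call. = FALSE)
    }
    per_measure <- purrr::map(measures, function(p) {
      map_one_series(s$velocity, p, nss_ms, nemr_ms, rate_hz)
    })
    ids <- s[1, series_id_cols]
    dplyr::bind_cols(ids[rep(1, sum(purrr::map_int(per_measure, nrow))), ],
                     dplyr::bind_rows(per_measure))
  })
  out <- dplyr::bind_rows(res)
  n_missing <- sum(is.na(out$value))
  if (n_missing > 0L) {
    warning(n_missing, " map cell(s) could not be evaluated and are NA.",
            call. = FALSE)
  }
  out
}

#' Average maps cell-wise across series
#'
#' @param maps Long map tibble from [build_maps()].
#' @return A tibble with one row per measure x cell: the across-series mean
#'   of non-missing values (`value`), the number of series contributing
#'   (`n_series`). A cell is NA only if missing in every series.
#' @export
average_maps <- function(maps) {
  out <- maps |>
    dplyr::group_by(.data$measure, .data$level, .data$index,
                    .data$start_ms, .data$end_ms, .data$length_ms) |>
    dplyr::summarise(n_series = sum(!is.na(.data$value)),
                     value = dplyr::if_else(sum(!is.na(.data$value)) > 0L,
                                            mean(.data$value, na.rm = TRUE),
                                            NA_real_),
                     .groups = "drop")
  class(out) <- c("oculomap_avg", class(out))
  out
}

#' Min-max normalise values to [0, 1]
#'
#' The affine map `(x - min) / (max - min)` applied to a vector. Degenerate
#' input (all values equal) raises an error rather than dividing by zero.
#'
#' @param x Numeric vector with at least two distinct finite values.
#' @return Numeric vector in [0, 1]; the minimum maps to 0, the maximum
#'   to 1. NA values pass through.
#' @export
#' @examples
#' normalize_minmax(c(2, 4, 6))
normalize_minmax <- function(x) {
  fin <- x[is.finite(x)]
  if (length(fin) < 2L || diff(range(fin)) == 0) {
    stop("Degenerate range: need at least two distinct finite values.",
         call. = FALSE)
  }
  (x - min(fin)) / (max(fin) - min(fin))
}

#' Min-max normalise map cells per measure and level
#'
#' Adds a `value_norm` column: each (measure, level) stratum is rescaled to
#' [0, 1] with the min and max pooled over all series and segment indices of
#' that stratum — the normalisation applied before feature-vector assembly
#' (and hence before cross-validation splitting). For a leakage-free
#' alternative fit on training folds only, see the `normalization` argument
#' of [knn_loso_cv()]. Degenerate strata (all values equal) are flagged NA
#' with a warning.
#'
#' @param maps Long map tibble from [build_maps()].
#' @return The input tibble with a `value_norm` column in [0, 1].
#' @export
normalize_maps <- function(maps) {
  maps |>
    dplyr::group_by(.data$measure, .data$level) |>
    dplyr::group_modify(function(df, key) {
      df$value_norm <- tryCatch(
        normalize_minmax(df$value),
        error = function(e) {
          warning("Degenerate stratum ", key$measure, " level ", key$level,
                  ": normalised values set to NA.", call. = FALSE)
          rep(NA_real_, nrow(df))
        })
      df
    }) |>
    dplyr::ungroup()
}
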