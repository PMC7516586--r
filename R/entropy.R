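# Regularity measures: approximate entropy and fuzzy entropy.
#
# Both operate on a scalar velocity series u(1), ..., u(N) and compare the
# log-frequency of m-sample pattern matches with (m+1)-sample matches within
# a tolerance r. ApEn counts hard (Chebyshev) matches and includes the
# self-match; FuzEn scores similarity with the exponential membership
# exp(-d^n / r) on baseline-removed patterns and excludes the self-match.
# Natural logarithms throughout; results are in nats.

check_series <- function(u, m, what = "series") {
  if (!is.numeric(u)) {
    stop("`", what, "` must be a numeric vector.", call. = FALSE)
  }
  if (anyNA(u) || any(!is.finite(u))) {
    stop("`", what, "` contains non-finite samples.", call. = FALSE)
  }
  if (length(u) < m + 2) {
    stop("`", what, "` has ", length(u), " samples; at least m + 2 = ",
         m + 2, " are required.", call. = FALSE)
  }
  invisible(u)
}

check_tolerance <- function(r_abs) {
  if (!is.numeric(r_abs) || length(r_abs) != 1L || !is.finite(r_abs) ||
      r_abs <= 0) {
    stop("`r_abs` must be a single positive number (got ",
         format(r_abs), "). A constant series has zero spread and yields ",
         "no usable tolerance.", call. = FALSE)
  }
  invisible(r_abs)
}

#' Population standard deviation of a series
#'
#' The tolerance scale used by [approximate_entropy()] and [fuzzy_entropy()]
#' is a coefficient times the standard deviation of the full parent velocity
#' series. The population convention (divide by N) is used; at the series
#' lengths this package works with (64-1024 samples) the difference from the
#' sample convention is negligible, but one convention has to be fixed.
#'
#' @param u Numeric vector with at least two samples.
#' @return A single non-negative number. A constant series returns 0, which
#'   downstream entropy calls reject as a degenerate tolerance.
#' @export
#' @examples
#' series_sd(c(1, -1, 1, -1)) # 1
series_sd <- function(u) {
  if (!is.numeric(u) || length(u) < 2L) {
    stop("`u` must be a numeric vector with at least 2 samples.",
         call. = FALSE)
  }
  if (anyNA(u) || any(!is.finite(u))) {
    stop("`u` contains non-finite samples.", call. = FALSE)
  }
  sqrt(mean((u - mean(u))^2))
}

# Chebyshev pattern-distance matrix between all m-length patterns of u,
# built from the lag-0 absolute-difference matrix by shifting its diagonal.
chebyshev_pattern_dist <- function(u, m) {
  n_pat <- length(u) - m + 1L
  d1 <- abs(outer(u, u, "-"))
  d <- d1[seq_len(n_pat), seq_len(n_pat), drop = FALSE]
  if (m > 1L) {
    for (k in seq_len(m - 1L)) {
      idx <- seq_len(n_pat) + k
      d <- pmax(d, d1[idx, idx, drop = FALSE])
    }
  }
  d
}

apen_phi <- function(u, m, r_abs) {
  n_pat <- length(u) - m + 1L
  d <- chebyshev_pattern_dist(u, m)
  # self-match included: the diagonal is 0 <= r, so every count is >= 1
  ci <- rowSums(d <= r_abs) / n_pat
  mean(log(ci))
}

#' Approximate entropy of a scalar series
#'
#' Estimates ApEn(m, r, N) = Phi^m(r) - Phi^{m+1}(r), where Phi^m is the
#' average log-probability that two m-sample patterns agree within `r_abs`
#' under the Chebyshev (maximum-coordinate) distance. Self-matches are
#' included in the pattern counts, so every match probability is strictly
#' positive and the estimator is defined for any series.
#'
#' The absolute tolerance is supplied by the caller; for map building it is
#' `r_coef` times the standard deviation of the full parent velocity series
#' (default coefficient 0.2), not of the segment under evaluation.
#'
#' @param u Numeric vector, the series (velocity samples, deg/s).
#' @param m Pattern length (default 2).
#' @param r_abs Absolute tolerance, a positive number.
#' @return A single number, >= 0 up to floating-point rounding. Lower values
#'   mean more regular (more self-similar) dynamics.
#' @seealso [fuzzy_entropy()], [series_sd()]
#' @export
#' @examples
#' set.seed(1)
#' u <- rnorm(128)
#' approximate_entropy(u, m = 2, r_abs = 0.2 * series_sd(u))
approximate_entropy <- function(u, m = 2L, r_abs) {
  m <- as.integer(m)
  if (m < 1L) stop("`m` must be >= 1.", call. = FALSE)
  check_series(u, m)
  check_tolerance(r_abs)
  apen_phi(u, m, r_abs) - apen_phi(u, m + 1L, r_abs)
}

# Baseline-removed patterns: row i is u(i), ..., u(i+m-1) minus its own mean.
centered_patterns <- function(u, m) {
  n_pat <- length(u) - m + 1L
  x <- vapply(seq_len(m) - 1L,
              function(k) u[seq_len(n_pat) + k],
              numeric(n_pat))
  x <- matrix(x, nrow = n_pat)
  x - rowMeans(x)
}

fuzen_phi <- function(u, m, n, r_abs, n_use) {
  x <- centered_patterns(u, m)[seq_len(n_use), , drop = FALSE]
  d <- abs(outer(x[, 1L], x[, 1L], "-"))
  if (m > 1L) {
    for (k in 2:m) d <- pmax(d, abs(outer(x[, k], x[, k], "-")))
  }
  sim <- exp(-(d^n) / r_abs)
  # exclude self-similarity (the diagonal, identically 1)
  mean((rowSums(sim) - 1) / (n_use - 1L))
}

#' Fuzzy entropy of a scalar series
#'
#' Estimates FuzEn(m, n, r, N) = ln phi^m - ln phi^{m+1}. Patterns are first
#' baseline-removed (each subtracts its own mean), their Chebyshev distance d
#' is scored with the fuzzy membership exp(-d^n / r_abs), and phi^m averages
#' the similarity of each pattern to all others, self-matches excluded. Both
#' phi^m and phi^{m+1} average over the N - m patterns for which the
#' (m+1)-length extension exists.
#'
#' @param u Numeric vector, the series.
#' @param m Pattern length (default 2).
#' @param n Gradient of the fuzzy boundary (default 2).
#' @param r_abs Width of the fuzzy boundary, a positive number; for map
#'   building 0.075 times the parent-series standard deviation.
#' @return A single number, >= 0 up to rounding; phi values lie in (0, 1].
#' @export
#' @examples
#' set.seed(1)
#' u <- rnorm(128)
#' fuzzy_entropy(u, m = 2, n = 2, r_abs = 0.075 * series_sd(u))
fuzzy_entropy <- function(u, m = 2L, n = 2, r_abs) {
  m <- as.integer(m)
  if (m < 1L) stop("`m` must be >= 1.", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n <= 0) {
    stop("`n` must be a single positive number.", call. = FALSE)
  }
  check_series(u, m)
  check_tolerance(r_abs)
  n_use <- length(u) - m
  phi_m <- fuzen_phi(u, m, n, r_abs, n_use)
  phi_m1 <- fuzen_phi(u, m + 1L, n, r_abs, n_use)
  if (phi_m1 <= 0 || phi_m <= 0) {
    stop("Degenerate fuzzy similarity: phi underflowed to 0 ",
         "(tolerance far too small for this series).", call. = FALSE)
  }
  log(phi_m) - log(phi_m1)
}

#' Sweep fuzzy-entropy parameters over a collection of series
#'
#' Diagnostic used to choose the fuzzy-boundary parameters: for every
#' (n, r_coef) pair, fuzzy entropy is computed on each series of a
#' calibration collection (with `r_abs = r_coef * series_sd(series)`), and
#' the across-series standard deviation of the values is tabulated. The
#' parameter region where this SD starts to decrease slowly is the usual
#' choice; selection itself is left to the user.
#'
#' @param data A data frame with one row per sample, containing a series
#'   identifier column `series` and a `velocity` column, or a list of
#'   numeric vectors.
#' @param n_grid Numeric vector of candidate boundary gradients.
#' @param r_coef_grid Numeric vector of candidate width coefficients.
#' @param m Pattern length (default 2).
#' @return A tibble with one row per (n, r_coef) pair: columns `n`,
#'   `r_coef`, `sd_fuzen` (SD across series, NA if no series succeeded) and
#'   `n_series_ok` (how many series produced a value; failures are recorded
#'   as missing, not fatal).
#' @export
fuzen_param_sweep <- function(data, n_grid, r_coef_grid, m = 2L) {
  if (is.data.frame(data)) {
    if (!all(c("series", "velocity") %in% names(data))) {
      stop("`data` needs columns `series` and `velocity`.", call. = FALSE)
    }
    series_list <- split(data$velocity, data$series)
  } else if (is.list(data)) {
    series_list <- data
  } else {
    stop("`data` must be a data frame or a list of numeric vectors.",
         call. = FALSE)
  }
  if (length(series_list) == 0L) stop("Empty series collection.", call. = FALSE)
  if (length(n_grid) == 0L || length(r_coef_grid) == 0L) {
    stop("Parameter grids must be non-empty.", call. = FALSE)
  }
  sds <- vapply(series_list, series_sd, numeric(1))
  grid <- tidyr::expand_grid(n = as.numeric(n_grid),
                             r_coef = as.numeric(r_coef_grid))
  res <- purrr::pmap(grid, function(n, r_coef) {
    vals <- purrr::map2_dbl(series_list, sds, function(u, s) {
      tryCatch(fuzzy_entropy(u, m = m, n = n, r_abs = r_coef * s),
               error = function(e) NA_real_)
    })
    ok <- sum(!is.na(vals))
    tibble::tibble(
      sd_fuzen = if (ok >= 2L) stats::sd(vals, na.rm = TRUE) else NA_real_,
      n_series_ok = ok
    )
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(res))
}
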