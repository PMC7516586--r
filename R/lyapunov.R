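# State-space reconstruction and largest-Lyapunov-exponent estimation.
#
# A scalar series is delay-embedded (Takens), the time lag chosen at the
# first minimum of the lagged mutual information and the dimension by the
# false-nearest-neighbour criterion. The LLE is then estimated from the
# divergence of nearest-neighbour pairs, either as the average one-step
# log-divergence rate at a fixed horizon ("horizon_average") or as the
# least-squares slope of the mean log-divergence curve ("rosenstein_slope").

#' Delay-coordinate embedding
#'
#' Builds the M = N - (m-1)*tau state vectors
#' x_i = (u_i, u_{i+tau}, ..., u_{i+(m-1)tau}).
#'
#' @param u Numeric vector of length N.
#' @param m Embedding dimension (>= 1).
#' @param tau Time lag in samples (>= 1).
#' @return An M x m numeric matrix; row i is the state at time i.
#' @export
#' @examples
#' delay_embed(1:5, m = 2, tau = 1)
delay_embed <- function(u, m, tau) {
  m <- as.integer(m); tau <- as.integer(tau)
  if (m < 1L || tau < 1L) stop("`m` and `tau` must be >= 1.", call. = FALSE)
  n <- length(u)
  M <- n - (m - 1L) * tau
  if (M < 2L) {
    stop("Series of length ", n, " too short to embed with m = ", m,
         ", tau = ", tau, " (needs N >= (m-1)*tau + 2).", call. = FALSE)
  }
  out <- vapply(seq_len(m) - 1L,
                function(k) u[seq_len(M) + k * tau],
                numeric(M))
  matrix(out, nrow = M, ncol = m)
}

# Histogram mutual information (nats) between u_t and u_{t+lag}.
lagged_mi <- function(u, lag, bins) {
  n <- length(u) - lag
  brks <- seq(min(u), max(u), length.out = bins + 1L)
  xi <- findInterval(u, brks, rightmost.closed = TRUE, all.inside = TRUE)
  a <- xi[seq_len(n)]
  b <- xi[seq_len(n) + lag]
  joint <- table(factor(a, levels = seq_len(bins)),
                 factor(b, levels = seq_len(bins))) / n
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
}

#' Select an embedding lag by lagged mutual information
#'
#' Computes the histogram-estimated mutual information between the series
#' and its lagged copy for lags 1..`max_lag` and returns the first local
#' minimum, the standard lag choice for delay embedding. To suppress
#' single-lag binning ripple, the curve is lightly smoothed (3-point
#' running mean) and a candidate lag must undercut every smoothed value
#' within `window` lags on both sides. When no such minimum exists, or the
#' curve never rises meaningfully above the finite-sample independence bias
#' (roughly (bins-1)^2 / 2N nats — the case for white noise, which has no
#' preferred lag), the lag minimising raw MI is returned and the `fallback`
#' attribute is set.
#'
#' @param u Numeric vector; must not be constant.
#' @param max_lag Largest candidate lag (must be < N/2).
#' @param bins Number of histogram bins per axis (default 16).
#' @param window Dominance half-width for the minimum search (default 3).
#' @return An integer lag, with attributes `fallback` (logical) and `mi`
#'   (the raw MI curve, one value per lag).
#' @export
select_lag_mi <- function(u, max_lag = 50L, bins = 16L, window = 3L) {
  max_lag <- as.integer(max_lag); bins <- as.integer(bins)
  window <- max(1L, as.integer(window))
  n <- length(u)
  if (max_lag < 1L || max_lag >= n / 2) {
    stop("`max_lag` must be in [1, N/2).", call. = FALSE)
  }
  if (diff(range(u)) == 0) {
    stop("Constant series: mutual information undefined.", call. = FALSE)
  }
  mi <- vapply(seq_len(max_lag), function(l) lagged_mi(u, l, bins),
               numeric(1))
  ms <- as.numeric(stats::filter(mi, rep(1 / 3, 3), sides = 2))
  ms[1L] <- mi[1L]; ms[max_lag] <- mi[max_lag]
  cand <- NA_integer_
  for (t in seq_len(max_lag - window)) {
    nb <- ms[setdiff(max(1L, t - window):(t + window), t)]
    if (all(ms[t] < nb)) { cand <- t; break }
  }
  bias <- (bins - 1L)^2 / (2 * n)
  fallback <- is.na(cand) || max(mi) < 2 * bias
  lag <- if (fallback) which.min(mi) else cand
  structure(as.integer(lag), fallback = fallback, mi = mi)
}

#' Select an embedding dimension by false nearest neighbours
#'
#' For each candidate dimension m, every point's nearest neighbour in the
#' m-dimensional embedding is tested when the embedding is extended to
#' m + 1: the neighbour is false if the extra coordinate separates the pair
#' by more than `rtol` times their m-dimensional distance, or moves them
#' apart by more than `atol` series standard deviations. The smallest m with
#' a false-neighbour fraction below 1% is returned; if none qualifies (the
#' case for noise, which has no finite embedding), `max_m` is returned with
#' the `fallback` attribute set.
#'
#' @param u Numeric vector.
#' @param tau Embedding lag in samples.
#' @param max_m Largest dimension tried (default 8).
#' @param rtol Relative distance-increase threshold (default 15).
#' @param atol Absolute threshold in series-SD units (default 2).
#' @return An integer dimension with attributes `fallback` (logical) and
#'   `fnn_fraction` (per-dimension false-neighbour fractions).
#' @export
select_dim_fnn <- function(u, tau, max_m = 8L, rtol = 15, atol = 2) {
  tau <- as.integer(tau); max_m <- as.integer(max_m)
  if (max_m < 2L) stop("`max_m` must be >= 2.", call. = FALSE)
  n <- length(u)
  if (n < max_m * tau + 2L) {
    stop("Series too short to test dimensions up to ", max_m,
         " at tau = ", tau, ".", call. = FALSE)
  }
  sd_u <- series_sd(u)
  if (sd_u == 0) stop("Constant series: FNN undefined.", call. = FALSE)
  frac <- numeric(max_m)
  for (m in seq_len(max_m)) {
    y <- delay_embed(u, m, tau)
    # only points whose (m+1)-th coordinate exists can be tested
    M_next <- n - m * tau
    if (M_next < 2L) {
      frac[m] <- NA_real_
      next
    }
    y <- y[seq_len(M_next), , drop = FALSE]
    d2 <- as.matrix(stats::dist(y))^2
    diag(d2) <- Inf
    nn <- max.col(-d2, ties.method = "first")
    d_m <- sqrt(d2[cbind(seq_len(M_next), nn)])
    extra <- abs(u[seq_len(M_next) + m * tau] - u[nn + m * tau])
    # exact revisits (periodic signals) give d_m ~ 0 with extra ~ 1 ulp;
    # treat anything below numerical noise as a true neighbour
    eps <- 1e-8 * sd_u
    false_rel <- ifelse(d_m > eps, extra / d_m > rtol, extra > eps)
    false_abs <- sqrt(d_m^2 + extra^2) / sd_u > atol
    frac[m] <- mean(false_rel | false_abs)
  }
  ok <- which(!is.na(frac) & frac < 0.01)
  fallback <- length(ok) == 0L
  m_sel <- if (fallback) max_m else ok[1L]
  structure(as.integer(m_sel), fallback = fallback, fnn_fraction = frac)
}

#' Largest Lyapunov exponent from nearest-neighbour divergence
#'
#' Embeds the series, pairs every reference state with its nearest neighbour
#' (Euclidean distance, neighbours closer than `min_sep` samples in time
#' excluded, Theiler-style), and tracks the pair separation d_j(i) over i
#' time steps.
#'
#' * `mode = "horizon_average"`: the exponent is the average over all valid
#'   reference states of ln(d_j(i)/d_j(0)) / (i * dt) at the single horizon
#'   `i = follow_steps`.
#' * `mode = "rosenstein_slope"`: the exponent is the least-squares slope of
#'   the mean log-separation curve <ln d_j(i)> against i * dt over
#'   i = 1..`follow_steps` — the robust estimator for short noisy series.
#'
#' Positive values indicate exponential divergence of neighbouring
#' trajectories (chaos), negative values convergence. Pairs with zero
#' initial separation are skipped; if no pair survives, an error is raised.
#'
#' @param u Numeric vector.
#' @param m,tau Embedding dimension and lag (see [select_dim_fnn()],
#'   [select_lag_mi()]).
#' @param follow_steps Divergence horizon i, in samples (default 10).
#' @param dt Sampling interval in seconds (default 0.001, i.e. 1000 Hz);
#'   the exponent is reported per unit of `dt` x samples, so with the
#'   default it is in 1/s.
#' @param min_sep Temporal exclusion window for neighbour search, in
#'   samples; default `m * tau`.
#' @param mode `"horizon_average"` (default) or `"rosenstein_slope"`.
#' @return A single number, the estimated exponent.
#' @export
#' @examples
#' # fully chaotic logistic map: exponent ln 2 per iteration
#' x <- numeric(2000); x[1] <- 0.4
#' for (i in 2:2000) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
#' largest_lyapunov(x, m = 2, tau = 1, follow_steps = 5, dt = 1,
#'                  mode = "rosenstein_slope")
largest_lyapunov <- function(u, m, tau, follow_steps = 10L, dt = 0.001,
                             min_sep = NULL,
                             mode = c("horizon_average", "rosenstein_slope")) {
  mode <- match.arg(mode)
  m <- as.integer(m); tau <- as.integer(tau)
  follow_steps <- as.integer(follow_steps)
  if (follow_steps < 1L) stop("`follow_steps` must be >= 1.", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be > 0.", call. = FALSE)
  if (is.null(min_sep)) min_sep <- m * tau
  min_sep <- max(1L, as.integer(min_sep))

  y <- delay_embed(u, m, tau)
  M <- nrow(y)
  n_ref <- M - follow_steps
  if (n_ref < 2L) {
    stop("Too few state vectors (", M, ") for a divergence horizon of ",
         follow_steps, " steps.", call. = FALSE)
  }
  # a Theiler window wider than ~n/4 leaves central references with no
  # admissible neighbour at all; cap it for short segments
  min_sep <- min(min_sep, max(1L, n_ref %/% 4L))
  d <- as.matrix(stats::dist(y))
  # neighbour candidates: temporally separated, and followable for the full
  # horizon; references likewise
  cand <- d[seq_len(n_ref), seq_len(n_ref), drop = FALSE]
  off <- abs(outer(seq_len(n_ref), seq_len(n_ref), "-"))
  cand[off < min_sep] <- Inf
  # neighbours with (numerically) coincident states carry no divergence
  # information: exactly periodic signals revisit states to within float
  # rounding, and log-ratios of rounding noise would masquerade as
  # divergence; search among genuinely distinct states only
  floor0 <- 1e-9 * stats::sd(u)
  cand[cand <= floor0] <- Inf
  nn <- max.col(-cand, ties.method = "first")
  d0 <- cand[cbind(seq_len(n_ref), nn)]
  valid <- is.finite(d0)
  if (!any(valid)) {
    stop("Degenerate neighbours: every nearest-neighbour pair has zero ",
         "or undefined initial separation.", call. = FALSE)
  }
  ref <- which(valid)
  nn <- nn[valid]
  d0 <- d0[valid]

  if (mode == "horizon_average") {
    di <- d[cbind(ref + follow_steps, nn + follow_steps)]
    keep <- di > 0
    if (!any(keep)) {
      stop("Degenerate neighbours: all followed pairs collapsed to zero ",
           "separation.", call. = FALSE)
    }
    mean(log(di[keep] / d0[keep])) / (follow_steps * dt)
  } else {
    # mean log-separation curve including i = 0 (the initial separations),
    # then the least-squares slope over the divergence horizon
    mean_ln <- vapply(0:follow_steps, function(i) {
      di <- d[cbind(ref + i, nn + i)]
      keep <- di > 0
      if (!any(keep)) return(NA_real_)
      mean(log(di[keep]))
    }, numeric(1))
    tt <- (0:follow_steps) * dt
    ok <- !is.na(mean_ln)
    if (sum(ok) < 2L) {
      stop("Degenerate neighbours: log-separation curve undefined.",
           call. = FALSE)
    }
    unname(stats::coef(stats::lm(mean_ln[ok] ~ tt[ok]))[2L])
  }
}
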