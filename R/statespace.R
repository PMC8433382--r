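# Lag-based output-null/output-potent analysis: tune each unit to the
# anterior-posterior paw velocity across lags, reduce the population tuning
# to its top two principal components, define the potent axis at the
# execution lag, and relate potent/null dominance to the frequency content
# of the reduced trajectory.

#' Lag-tuning matrix, reduced trajectory and output-potent/null axes
#'
#' For every unit and every lag in -1 to 1 s (10 ms steps, 201 lags) the
#' tuning is the time average of the product of the anterior-posterior paw
#' velocity with the unit's activity at that lag
#' (`mean_t[v_AP(t) * r_n(t + lag)]`; negative lag = activity precedes the
#' movement). The N x 201 matrix is mean-centered across lags and reduced to
#' the top two principal components. The output-potent axis is the
#' normalized trajectory point at the execution lag (default -40 ms, the lag
#' at which the correlation with the mean planning-lag tuning is smallest);
#' the output-null axis is orthogonal to it. The per-lag state tuning is
#' `|<traj, potent>| - |<traj, null>|`.
#'
#' @param sess a [session()] with >= 3 units, or a numeric tuning matrix
#'   N x 201 (then `behavior` is not needed).
#' @param rate_sigma rate smoothing SD (s).
#' @param max_lag lag range half width in seconds (default 1).
#' @param execution_lag lag defining the potent axis in seconds
#'   (default -0.04); set `NULL` to re-derive it per session as the lag in
#'   -0.1..0 s whose trajectory correlates least, in absolute value, with
#'   the mean trajectory over the planning lags -1 to -0.2 s.
#' @param ap_axis which velocity component is anterior-posterior (default 1,
#'   i.e. vx).
#' @return object of class `state_space_result`: list with `tuning`
#'   (N x 201), `trajectory` (2 x 201), `potent`, `null` (unit 2-vectors),
#'   `state_tuning` (201), `lags_s`, `execution_lag`.
#' @export
lag_tuning_projection <- function(sess, rate_sigma = 0.05, max_lag = 1,
                                  execution_lag = -0.04, ap_axis = 1L) {
  if (inherits(sess, "session")) {
    beh <- sess$behavior
    dt <- beh$dt
    v_ap <- if (ap_axis == 1L) beh$vx else beh$vy
    n <- length(beh)
    if (length(sess$units) < 3) stopf("need >= 3 units")
    L <- round(max_lag / dt)
    lags <- seq(-L, L)
    tuning <- t(vapply(sess$units, function(u) {
      r <- instantaneous_rate(u, sess$duration, dt, rate_sigma)
      # mean_t v_ap(t) r(t + lag)
      xcorr_sums(v_ap, r, L) / xcorr_sums(rep(1, n), rep(1, n), L)
    }, numeric(2L * L + 1L)))
  } else {
    tuning <- sess
    dt <- 0.01
    L <- (ncol(tuning) - 1L) %/% 2L
  }
  lags_s <- seq(-L, L) * dt
  centered <- sweep(tuning, 1L, rowMeans(tuning))
  pc <- tryCatch(stats::prcomp(t(centered), center = FALSE, rank. = 2L),
                 error = function(e) NULL)
  if (is.null(pc) || ncol(pc$rotation) < 2L || pc$sdev[2L] < 1e-12)
    stopf("tuning matrix has rank < 2; state space undefined")
  traj <- t(pc$x[, 1:2]) # 2 x 201
  if (is.null(execution_lag)) {
    cand <- which(lags_s >= -0.1 & lags_s <= 0)
    plan_mean <- rowMeans(traj[, lags_s >= -1 & lags_s <= -0.2, drop = FALSE])
    cors <- vapply(cand, function(i)
      abs(sum(traj[, i] * plan_mean) /
            (sqrt(sum(traj[, i]^2)) * sqrt(sum(plan_mean^2)))), 0)
    execution_lag <- lags_s[cand[which.min(cors)]]
  }
  i_exec <- which.min(abs(lags_s - execution_lag))
  pvec <- traj[, i_exec]
  if (sqrt(sum(pvec^2)) == 0) stopf("zero trajectory at the execution lag")
  potent <- pvec / sqrt(sum(pvec^2))
  null_ax <- c(-potent[2L], potent[1L])
  state_tuning <- abs(colSums(traj * potent)) - abs(colSums(traj * null_ax))
  structure(list(tuning = tuning, trajectory = traj, potent = potent,
                 null = null_ax, state_tuning = state_tuning, lags_s = lags_s,
                 execution_lag = execution_lag, dt = dt),
            class = "state_space_result")
}

#' @export
print.state_space_result <- function(x, ...) {
  cat(sprintf("<state_space_result> %d units x %d lags, execution lag %+.0f ms\n",
              nrow(x$tuning), length(x$lags_s), 1000 * x$execution_lag))
  invisible(x)
}

#' Relate frequency dominance to output-potent/null coding
#'
#' Treats the reduced 2 x 201 trajectory as a signal over the lag axis,
#' band-splits it at `split` Hz (subtractive-Gaussian high-pass; the low
#' band is the complementary smoothed component with its mean removed), and
#' takes the Euclidean norm over the two components as the high- and
#' low-frequency amplitudes per lag. Lags are pooled by the sign of the
#' frequency tuning (high minus low amplitude) and the mean state tuning is
#' returned per pool: a positive mean in the high pool means dominant
#' high-frequency changes are associated with the output-potent space.
#'
#' @param result a [lag_tuning_projection()] result.
#' @param split split frequency in Hz (default 1.1).
#' @return list with `frequency_tuning` (per lag), `mean_state_high`,
#'   `mean_state_low`, `n_high`, `n_low`, `degenerate` (TRUE when a pool is
#'   empty).
#' @export
state_vs_frequency <- function(result, split = 1.1) {
  stopifnot(inherits(result, "state_space_result"))
  dt <- result$dt
  sigma <- 1 / (2 * pi * split)
  n_lag <- length(result$lags_s)
  if (n_lag * dt < 2 / split) stopf("trajectory too short for a %g Hz split", split)
  high <- low <- matrix(0, 2L, n_lag)
  for (k in 1:2) {
    sm <- gaussian_smooth(result$trajectory[k, ], sigma, dt)
    high[k, ] <- result$trajectory[k, ] - sm
    low[k, ] <- sm - mean(sm)
  }
  amp_high <- sqrt(colSums(high^2))
  amp_low <- sqrt(colSums(low^2))
  ftun <- amp_high - amp_low
  hi <- ftun > 0
  lo <- ftun < 0
  list(frequency_tuning = ftun,
       mean_state_high = if (any(hi)) mean(result$state_tuning[hi]) else NA_real_,
       mean_state_low = if (any(lo)) mean(result$state_tuning[lo]) else NA_real_,
       n_high = sum(hi), n_low = sum(lo),
       degenerate = !any(hi) || !any(lo))
}
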