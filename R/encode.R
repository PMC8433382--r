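# Kernel-based encoding (de-noising) of unit activity from paw velocity and
# the frequency-swept two-point decoder.
#
# All temporal-kernel least squares are solved on a circular (wrap-around)
# lag embedding: the Gram matrix of lagged regressors is then block Toeplitz
# and is assembled from FFT-based circular cross-correlations, which makes
# the T = 400 tap fits tractable on full sessions. For session lengths of
# minutes the wrap-around edge affects a negligible fraction of samples.

# Circular cross-correlation sums: ccf[k] = sum_t x(t) y(t + k mod n),
# returned for k = 0..n-1.
#' @keywords internal
#' @noRd
circ_ccf <- function(x, y) {
  n <- length(x)
  Re(stats::fft(Conj(stats::fft(x)) * stats::fft(y), inverse = TRUE)) / n
}

#' @keywords internal
#' @noRd
circ_at <- function(ccf, k) {
  n <- length(ccf)
  ccf[(k %% n) + 1L]
}

#' Least-squares temporal kernel linking lagged regressors to a target
#'
#' Solves `y(t) ~ sum_j sum_l w[j, l] x_j(t - l)` over the integer lags `l`
#' (bins) by normal equations on the circular lag embedding. Regressors and
#' target are centered internally; predictions add the target mean back.
#'
#' @param X numeric matrix `n x p` of regressors (columns).
#' @param y numeric target of length `n`.
#' @param lags integer vector of lags in bins (e.g. `-200:199` for the
#'   standard T = 400 kernel at 10 ms).
#' @param ridge small diagonal regularizer added when the Gram matrix is
#'   numerically singular (rank-deficient designs are flagged).
#' @return list with `weights` (`length(lags) x p`), `lags`, `prediction`
#'   (length `n`), `residual_sd`, `flag_regularized`.
#' @export
fit_lagged_kernel <- function(X, y, lags = -200:199, ridge = 1e-8) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  n <- nrow(X); p <- ncol(X); T_ <- length(lags)
  stopifnot(length(y) == n, T_ < n)
  Xc <- sweep(X, 2L, colMeans(X))
  yc <- y - mean(y)
  # circular ccfs between regressor pairs and regressor-target
  G <- matrix(0, p * T_, p * T_)
  b <- numeric(p * T_)
  for (j in seq_len(p)) {
    cj <- circ_ccf(Xc[, j], yc)
    b[(j - 1L) * T_ + seq_len(T_)] <- circ_at(cj, lags)
    for (k in j:p) {
      cc <- circ_ccf(Xc[, j], Xc[, k])
      # G[(j,l),(k,l')] = sum_t xj(t-l) xk(t-l') = ccf_jk[l - l']
      dmat <- outer(lags, lags, `-`)
      blk <- matrix(circ_at(cc, as.vector(dmat)), T_, T_)
      G[(j - 1L) * T_ + seq_len(T_), (k - 1L) * T_ + seq_len(T_)] <- blk
      if (k != j)
        G[(k - 1L) * T_ + seq_len(T_), (j - 1L) * T_ + seq_len(T_)] <- t(blk)
    }
  }
  flag <- FALSE
  w <- tryCatch(solve(G, b), error = function(e) NULL)
  if (is.null(w)) {
    flag <- TRUE
    w <- solve(G + diag(ridge * max(diag(G), 1), nrow(G)), b)
  }
  W <- matrix(w, T_, p)
  # prediction: sum_j circular convolution of xj with its kernel
  pred <- rep(mean(y), n)
  for (j in seq_len(p)) {
    kern <- numeric(n)
    kern[(lags %% n) + 1L] <- W[, j]
    pred <- pred + Re(stats::fft(stats::fft(Xc[, j]) * stats::fft(kern),
                                 inverse = TRUE)) / n
  }
  list(weights = W, lags = lags, prediction = pred,
       residual_sd = stats::sd(y - pred), flag_regularized = flag)
}

#' De-noise unit activity by encoding it from the paw velocity
#'
#' For every unit, fits the T x 2 temporal kernel (lags -2 to 2 s at 10 ms,
#' T = 400) that predicts the unit's Gaussian-smoothed instantaneous rate
#' from the vx and vy velocity traces by least squares. The de-noised
#' activity is the prediction; optionally, white Gaussian noise matching the
#' residual SD is added back to emulate the raw data's noise level.
#'
#' @param sess a [session()] of at least 60 s.
#' @param rate_sigma rate smoothing SD in seconds (default 0.05).
#' @param lags kernel lags in bins (default `-200:199`).
#' @param add_noise also return the noise-added variant (default FALSE).
#' @param seed seed for the noise-added variant.
#' @return object of class `encoding_fit`: list with `denoised` (units x
#'   bins), `kernels` (list of T x 2 matrices), `r2` (per-unit in-sample
#'   variance explained), `noisy` (units x bins or NULL), `lags`, `dt`.
#' @export
fit_encoding <- function(sess, rate_sigma = 0.05, lags = -200:199,
                         add_noise = FALSE, seed = 1) {
  stopifnot(inherits(sess, "session"))
  if (sess$duration < 60) stopf("session must be >= 60 s")
  beh <- sess$behavior
  n <- length(beh)
  X <- cbind(beh$vx, beh$vy)
  U <- length(sess$units)
  denoised <- matrix(0, U, n)
  noisy <- if (add_noise) matrix(0, U, n) else NULL
  kernels <- vector("list", U)
  r2 <- numeric(U)
  set.seed(as.integer(seed))
  for (u in seq_len(U)) {
    y <- instantaneous_rate(sess$units[[u]], sess$duration, beh$dt, rate_sigma)
    fit <- fit_lagged_kernel(X, y, lags)
    denoised[u, ] <- fit$prediction
    kernels[[u]] <- fit$weights
    r2[u] <- if (stats::sd(y) > 0) 1 - fit$residual_sd^2 / stats::var(y) else NA_real_
    if (add_noise)
      noisy[u, ] <- fit$prediction + stats::rnorm(n, sd = fit$residual_sd)
  }
  structure(list(denoised = denoised, kernels = kernels, r2 = r2,
                 noisy = noisy, lags = lags, dt = beh$dt),
            class = "encoding_fit")
}

#' @export
print.encoding_fit <- function(x, ...) {
  cat(sprintf("<encoding_fit> %d units, T = %d taps, median r2 = %.3f\n",
              nrow(x$denoised), length(x$lags), stats::median(x$r2, na.rm = TRUE)))
  invisible(x)
}

#' Frequency-swept two-point decoding of paw velocity
#'
#' For each band, the (de-noised) unit activities are band-pass filtered and
#' the paw velocity is decoded with a two-point kernel per unit and axis: one
#' weight reading the activity at lag 0 and one at lag -1/f (f the band
#' center, rounded to the 10 ms grid), fitted by least squares independently
#' per axis. Performance is the Pearson correlation between decoded and
#' measured velocity, averaged over the two axes.
#'
#' @param activity units x bins activity matrix (e.g. `fit_encoding()$denoised`
#'   or its `noisy` variant).
#' @param behavior a [behavior_trace()].
#' @param bands list of [band_spec()]s (default [default_bands()]).
#' @param split fit in-sample over the whole session (FALSE, default), or
#'   use a blocked 2-fold split -- fit on one half, evaluate on the other,
#'   both ways -- for an honest out-of-sample curve.
#' @return data.frame with `center_freq`, `performance`, `skipped`; attribute
#'   `best_band` holds the argmax center frequency.
#' @export
two_point_decode_sweep <- function(activity, behavior, bands = default_bands(),
                                   split = FALSE) {
  stopifnot(inherits(behavior, "behavior_trace"))
  if (is.null(dim(activity))) activity <- matrix(activity, nrow = 1)
  dt <- behavior$dt
  n <- ncol(activity)
  V <- cbind(behavior$vx, behavior$vy)
  half <- n %/% 2L
  perf <- rep(NA_real_, length(bands))
  skipped <- logical(length(bands))
  for (bi in seq_along(bands)) {
    band <- bands[[bi]]
    lag_bins <- round(1 / band$center_freq / dt)
    filt <- t(apply(activity, 1L, band_pass, band = band, dt = dt))
    if (all(apply(filt, 1L, stats::sd) == 0)) {
      skipped[bi] <- TRUE
      next
    }
    # design: per unit, activity at lag 0 and at -1/f (activity 1/f earlier)
    D <- cbind(1, t(filt), apply(filt, 1L, shift_series, k = lag_bins))
    rs <- NULL
    for (ax in 1:2) {
      if (!split) {
        fit <- stats::lm.fit(D, V[, ax])
        rs <- c(rs, pearson(fit$fitted.values, V[, ax]))
      } else {
        for (fold in 1:2) {
          train <- if (fold == 1L) seq_len(half) else (half + 1L):n
          test <- setdiff(seq_len(n), train)
          w <- stats::lm.fit(D[train, , drop = FALSE], V[train, ax])$coefficients
          w[is.na(w)] <- 0
          rs <- c(rs, pearson(D[test, , drop = FALSE] %*% w, V[test, ax]))
        }
      }
    }
    perf[bi] <- mean(rs)
  }
  res <- data.frame(center_freq = vapply(bands, `[[`, 0, "center_freq"),
                    performance = perf, skipped = skipped, row.names = NULL)
  attr(res, "best_band") <- res$center_freq[which.max(res$performance)]
  res
}
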