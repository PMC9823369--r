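#' Autocovariance of a long-axis-length series
#'
#' Stationary autocovariance of the fluctuation of the long-axis length
#' around its time average,
#' `C(tau_j) = (1/N) * sum_t (R(t + tau_j) - Rbar)(R(t) - Rbar)` for the
#' biased estimator (`1/(N - j)` for the unbiased one), with `Rbar` the
#' sample mean and the lag grid the integer multiples of the frame
#' interval. `C(0)` of the biased estimator is exactly the (1/N) sample
#' variance, the quantity the spring constant is read from.
#'
#' The biased estimator is the default: it keeps `|C(tau)| <= C(0)` and
#' the estimated curve positive semi-definite, which stabilizes the
#' damped-cosine fit; the unbiased version is available for comparison.
#'
#' Frames flagged by the extractor must not reach this estimator (gaps
#' would bias the lag products); pass only `flag == "ok"` frames of a
#' contiguous record, or the function errors.
#'
#' @param series A data frame with columns `time_s` and `R_um` for a
#'   single molecule (one evenly sampled record). A `flag` column, if
#'   present, must be all `"ok"`.
#' @param max_lag_s Maximum lag in seconds (default 2). Must not exceed a
#'   third of the record length.
#' @param estimator `"biased"` (default) or `"unbiased"`.
#' @param gaps `"error"` (default): refuse series with missing frames;
#'   `"pairwise"`: average the lag products over the pairs actually
#'   observed on the frame grid (no interpolation; for the biased
#'   estimator the per-lag mean is rescaled by `(N - j)/N` so the
#'   gap-free limit matches the standard estimator exactly).
#' @return A tibble with columns `lag_s`, `C_um2`, `n_pairs`, and
#'   attribute `estimator`.
#' @examples
#' p <- oscillator_params(k = 12e-9, gamma = 3, omega = 6)
#' s <- simulate_gp(p, sampling_spec(n_frames = 600, n_molecules = 1, seed = 1))
#' autocovariance(s, max_lag_s = 1)
#' @export
autocovariance <- function(series, max_lag_s = 2, estimator = c("biased", "unbiased"),
                           gaps = c("error", "pairwise")) {
  estimator <- match.arg(estimator)
  gaps <- match.arg(gaps)
  stopifnot(is.data.frame(series))
  if (!all(c("time_s", "R_um") %in% names(series))) {
    abort("`series` needs columns `time_s` and `R_um`.")
  }
  if ("molecule_id" %in% names(series) && length(unique(series$molecule_id)) > 1L) {
    abort("`series` contains several molecules; fit per molecule (see `fit_molecules()`).")
  }
  if ("flag" %in% names(series) && any(series$flag != "ok")) {
    abort(paste0(
      "series contains flagged frames; filter to flag == \"ok\" on a ",
      "contiguous record before estimating the autocovariance ",
      "(interpolating or splicing over gaps would bias C(tau))."
    ))
  }
  x <- series$R_um
  n_obs <- length(x)
  if (n_obs < 50) abort("need at least 50 frames to estimate the autocovariance.")
  t_s <- series$time_s
  dts <- diff(t_s)
  dt <- min(dts)
  if (dt <= 0) abort("`time_s` must be strictly increasing.")
  ratio <- dts / dt
  if (any(abs(ratio - round(ratio)) > 1e-6)) {
    abort("`time_s` must lie on a regular frame grid (constant frame interval).")
  }
  gapped <- any(round(ratio) > 1)
  if (gapped && gaps == "error") {
    abort(paste0(
      "series has missing frames; re-extract, pass a contiguous segment, ",
      "or use gaps = \"pairwise\" (never interpolate over gaps)."
    ))
  }
  if (!gapped) {
    n <- n_obs
    max_lag_j <- floor(max_lag_s / dt + 1e-9)
    if (max_lag_j > floor(n / 3)) {
      abort("`max_lag_s` exceeds a third of the record length; shorten it.")
    }
    a <- acf(x, lag.max = max_lag_j, type = "covariance", plot = FALSE, demean = TRUE)
    cc <- as.numeric(a$acf)          # biased (1/N) normalization
    j <- 0:max_lag_j
    n_pairs <- n - j
    if (estimator == "unbiased") cc <- cc * n / n_pairs
  } else {
    # place observations on the full frame grid, average over observed pairs
    idx <- round((t_s - t_s[1]) / dt) + 1L
    n <- max(idx)
    max_lag_j <- floor(max_lag_s / dt + 1e-9)
    if (max_lag_j > floor(n / 3)) {
      abort("`max_lag_s` exceeds a third of the record length; shorten it.")
    }
    xf <- rep(0, n); of <- rep(0, n)
    xc <- x - mean(x)
    xf[idx] <- xc; of[idx] <- 1
    j <- 0:max_lag_j
    cc <- numeric(length(j)); n_pairs <- integer(length(j))
    for (i in seq_along(j)) {
      jj <- j[i]
      a1 <- seq_len(n - jj)
      p <- of[a1] * of[a1 + jj]
      n_pairs[i] <- sum(p)
      if (n_pairs[i] == 0) {
        cc[i] <- NA_real_
        next
      }
      cc[i] <- sum(xf[a1] * xf[a1 + jj]) / n_pairs[i]
      if (estimator == "biased") cc[i] <- cc[i] * (n - jj) / n
    }
  }
  out <- tibble(lag_s = j * dt, C_um2 = cc, n_pairs = as.integer(n_pairs))
  attr(out, "estimator") <- estimator
  attr(out, "n_frames") <- n
  attr(out, "frame_interval_s") <- dt
  out
}
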