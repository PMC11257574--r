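#' FRAP trace container
#'
#' Raw intensities over time for the bleached ROI, an unbleached
#' reference cell in the same image (acquisition-photobleaching
#' control) and an empty-space background ROI.
#'
#' @param times acquisition times in seconds, strictly increasing.
#' @param bleach,reference,background per-timepoint ROI intensities.
#' @param n_prebleach number of pre-bleach frames (>= 1); frame
#'   `n_prebleach + 1` is the first post-bleach frame.
#' @return A `frap_trace` object.
#' @export
frap_trace <- function(times, bleach, reference, background, n_prebleach) {
  n <- length(times)
  if (length(bleach) != n || length(reference) != n || length(background) != n) {
    stop("times, bleach, reference and background must have equal length")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (n_prebleach < 1L) stop("need at least one pre-bleach frame")
  if (n - n_prebleach < 5L) stop("need at least 5 post-bleach points")
  structure(list(times = as.numeric(times), bleach = as.numeric(bleach),
                 reference = as.numeric(reference),
                 background = as.numeric(background),
                 n_prebleach = as.integer(n_prebleach)),
            class = "frap_trace")
}

#' Read / write FRAP traces as CSV
#'
#' Columns: `time_s`, `bleach`, `reference`, `background`, `prebleach`
#' (0/1 flag).
#'
#' @param trace a [frap_trace()].
#' @param path CSV path.
#' @return `write_frap_trace`: `path`, invisibly; `read_frap_trace`: a
#'   [frap_trace()].
#' @export
write_frap_trace <- function(trace, path) {
  df <- data.frame(time_s = trace$times, bleach = trace$bleach,
                   reference = trace$reference,
                   background = trace$background,
                   prebleach = as.integer(seq_along(trace$times) <=
                                            trace$n_prebleach))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frap_trace
#' @export
read_frap_trace <- function(path) {
  df <- utils::read.csv(path)
  frap_trace(df$time_s, df$bleach, df$reference, df$background,
             n_prebleach = sum(df$prebleach == 1L))
}

#' Correct a FRAP trace for background and acquisition photobleaching
#'
#' Background is subtracted from both the bleached and the reference
#' ROI; the acquisition-photobleaching decay carried by the reference
#' (an unbleached cell in the same image) is divided out and rescaled
#' to the mean pre-bleach reference level:
#' `corrected(t) = (bleach(t) - background(t)) * Rbar /
#'  (reference(t) - background(t))`.
#'
#' @param trace a [frap_trace()].
#' @return numeric vector of corrected intensities.
#' @export
correct_trace <- function(trace) {
  ref <- trace$reference - trace$background
  bad <- which(ref <= 0)
  if (length(bad) > 0L) {
    stop("reference at or below background at timepoint ", bad[1L])
  }
  rbar <- mean(ref[seq_len(trace$n_prebleach)])
  (trace$bleach - trace$background) * rbar / ref
}

#' Normalize a corrected FRAP series
#'
#' Affine map sending the mean pre-bleach intensity to 100% and the
#' first post-bleach intensity to 0%, applied to every point. Applying
#' it twice is a no-op.
#'
#' @param corrected corrected intensities (from [correct_trace()]).
#' @param n_prebleach number of pre-bleach frames.
#' @return numeric vector, percent scale.
#' @export
normalize_trace <- function(corrected, n_prebleach) {
  pre <- mean(corrected[seq_len(n_prebleach)])
  post0 <- corrected[n_prebleach + 1L]
  if (pre <= post0) {
    stop("mean pre-bleach intensity must exceed the first post-bleach ",
         "intensity (no bleach detected)")
  }
  (corrected - post0) / (pre - post0) * 100
}

#' Rolling average of post-bleach points
#'
#' Centred moving mean (default window 3) over the post-bleach points
#' only, to damp acquisition noise; pre-bleach points pass through
#' untouched. At the series ends the window shrinks to the available
#' points.
#'
#' @param values intensity series (pre-bleach then post-bleach).
#' @param window odd window size (default 3).
#' @param n_prebleach leading points left untouched (default 0).
#' @return smoothed series, same length.
#' @export
rolling_average <- function(values, window = 3L, n_prebleach = 0L) {
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be a positive odd integer")
  }
  post <- values[(n_prebleach + 1L):length(values)]
  n <- length(post)
  if (n < window) stop("fewer post-bleach points than the window size")
  half <- (window - 1L) %/% 2L
  sm <- vapply(seq_len(n), function(i) {
    mean(post[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
  c(values[seq_len(n_prebleach)], sm)
}

#' Fit single-exponential FRAP recovery
#'
#' Least-squares fit of `y = m1 + m2 * exp(-m3 * x)` to the normalized
#' post-bleach series, with `x = 0` at the first post-bleach frame;
#' `m3` is the off-rate (1/s) and the recovery half-time is
#' `t1/2 = ln(2) / m3`. Initial values are deterministic: `m1` from the
#' mean of the last 10% of points, `m2` from the first value, `m3` from
#' a log-linear regression of `m1 - y`.
#'
#' When the series was smoothed before fitting, pass the same
#' `smoothing_window`: the model curve is then passed through the
#' identical rolling-average operator before comparison, so smoothing
#' introduces no parameter bias (a noiseless smoothed trace is fitted
#' exactly).
#'
#' @param times post-bleach times (s), `times[1]` taken as 0 origin.
#' @param values normalized (and possibly smoothed) post-bleach series.
#' @param smoothing_window `NULL` for a raw fit, or the odd window used
#'   to smooth `values`.
#' @return A `frap_fit`: list with `m1`, `m2`, `m3`, `t_half`, `rms`,
#'   `converged`.
#' @export
fit_recovery <- function(times, values, smoothing_window = NULL) {
  n <- length(values)
  if (length(times) != n) stop("times and values must have equal length")
  if (n < 5L) stop("need at least 5 post-bleach points to fit 3 parameters")
  if (diff(range(values)) == 0) stop("all values equal: nothing to fit")
  x <- times - times[1L]

  m1_0 <- mean(values[x >= stats::quantile(x, 0.9)])
  m2_0 <- values[1L] - m1_0
  if (m2_0 == 0) m2_0 <- -abs(m1_0) - 1
  # log-linear start for the rate, on points where m1 - y has the sign
  # of the amplitude
  resid0 <- (m1_0 - values) / -sign(m2_0)
  ok <- resid0 > 0 & x > 0
  m3_0 <- if (sum(ok) >= 2L) {
    sl <- stats::coef(stats::lm(log(resid0[ok]) ~ x[ok]))[[2L]]
    max(-sl, 1e-6)
  } else {
    log(2) / max(x[length(x)] / 4, 1e-6)
  }

  model <- function(p) {
    y <- p[1L] + p[2L] * exp(-p[3L] * x)
    if (!is.null(smoothing_window)) {
      y <- rolling_average(y, window = smoothing_window)
    }
    y
  }
  fit <- minpack.lm::nls.lm(
    par = c(m1 = m1_0, m2 = m2_0, m3 = m3_0),
    lower = c(-Inf, -Inf, 1e-12),
    fn = function(p) values - model(p),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  p <- fit$par
  converged <- fit$info %in% 1:4 && p[["m3"]] > 0
  structure(
    list(m1 = p[["m1"]], m2 = p[["m2"]], m3 = p[["m3"]],
         t_half = log(2) / p[["m3"]],
         rms = sqrt(mean(fit$fvec^2)), converged = converged),
    class = "frap_fit"
  )
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "frap_fit: y = %.3f + %.3f exp(-%.5f x); t1/2 = %.3f s (rms %.3g)%s\n",
    x$m1, x$m2, x$m3, x$t_half, x$rms,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Full FRAP analysis pipeline
#'
#' Correct for background and acquisition photobleaching, normalize to
#' the 100%/0% convention, rolling-average the post-bleach points
#' (default window 3; disable with `smooth = FALSE`) and fit the
#' single-exponential recovery.
#'
#' @param trace a [frap_trace()].
#' @param window smoothing window (odd, default 3).
#' @param smooth logical; fit the smoothed (default) or raw series.
#' @return list with `fit` (a `frap_fit`), `times` (post-bleach, 0 at
#'   first post-bleach frame), `normalized` and `smoothed` series
#'   (post-bleach portion).
#' @export
frap_fit_pipeline <- function(trace, window = 3L, smooth = TRUE) {
  corrected <- correct_trace(trace)
  normalized <- normalize_trace(corrected, trace$n_prebleach)
  post_idx <- (trace$n_prebleach + 1L):length(normalized)
  times <- trace$times[post_idx] - trace$times[post_idx[1L]]
  post <- normalized[post_idx]
  if (smooth) {
    smoothed <- rolling_average(post, window = window)
    fit <- fit_recovery(times, smoothed, smoothing_window = window)
  } else {
    smoothed <- post
    fit <- fit_recovery(times, post)
  }
  list(fit = fit, times = times, normalized = post, smoothed = smoothed)
}
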