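# Preprocessing of uniform series: resampling, detrending, filtering,
# sliding-window artifact detection, gap interpolation and z-scoring.
#
# Every operation preserves length, start time and sampling frequency
# (resample changes fs but preserves the covered extent to within one
# sample period), works per channel on multi-channel accelerometry, and
# never interpolates across missing data: NaN runs stay NaN unless
# fill_gaps() is asked to fill them.

# index runs of consecutive finite samples: matrix with columns first, last
finite_runs <- function(v) {
  ok <- is.finite(v)
  if (!any(ok)) return(matrix(numeric(0), 0, 2))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}

# modified-Akima (makima) slopes + piecewise-cubic Hermite evaluation
makima_interp <- function(x, y, xo) {
  n <- length(x)
  if (n == 1L) return(rep(y, length(xo)))
  if (n == 2L) return(stats::approx(x, y, xo, rule = 2)$y)
  d <- diff(y) / diff(x)
  dd <- c(2 * d[1] - d[2], d, 2 * d[n - 1] - d[n - 2])
  dd <- c(2 * dd[1] - dd[2], dd, 2 * dd[length(dd)] - dd[length(dd) - 1])
  # dd[i..i+3] = delta_{i-2}, delta_{i-1}, delta_i, delta_{i+1} for slope i
  dm2 <- dd[seq_len(n)]; dm1 <- dd[seq_len(n) + 1L]
  d0 <- dd[seq_len(n) + 2L]; dp1 <- dd[seq_len(n) + 3L]
  w1 <- abs(dp1 - d0) + abs(dp1 + d0) / 2
  w2 <- abs(dm1 - dm2) + abs(dm1 + dm2) / 2
  s <- ifelse(w1 + w2 == 0, 0, (w1 * dm1 + w2 * d0) / (w1 + w2))
  hermite_eval(x, y, s, xo)
}

hermite_eval <- function(x, y, s, xo) {
  n <- length(x)
  k <- findInterval(xo, x, rightmost.closed = TRUE)
  k[k < 1L] <- 1L; k[k >= n] <- n - 1L
  h <- x[k + 1L] - x[k]
  u <- (xo - x[k]) / h
  h00 <- (1 + 2 * u) * (1 - u)^2
  h10 <- u * (1 - u)^2
  h01 <- u^2 * (3 - 2 * u)
  h11 <- u^2 * (u - 1)
  y[k] * h00 + h * s[k] * h10 + y[k + 1L] * h01 + h * s[k + 1L] * h11
}

interp_core <- function(xi, yi, xo, method) {
  n <- length(xi)
  if (n == 0L) return(rep(NaN, length(xo)))
  if (n == 1L) return(rep(yi, length(xo)))
  if (n == 2L && method != "linear") method <- "linear"
  switch(method,
    linear = stats::approx(xi, yi, xo, rule = 2)$y,
    spline = stats::splinefun(xi, yi, method = "fmm")(xo),
    pchip = pracma::pchip(xi, yi, xo),
    makima = makima_interp(xi, yi, xo),
    stop("unknown interpolation method: ", method, call. = FALSE))
}

#' Resample a uniform series
#'
#' The output grid is anchored at the series start time at the new rate and
#' preserves the covered extent to within one sample period. Interpolation
#' never bridges missing data: each finite run is interpolated on its own
#' span and output samples outside every run are `NaN`. No anti-alias
#' filter is applied by default (down-sampling picks interpolated grid
#' values); set `anti_alias = TRUE` to low-pass at 0.45 x the new rate
#' first.
#'
#' @param series a [uniform_series()].
#' @param new_fs target sampling frequency in Hz.
#' @param method `"linear"`, `"spline"`, `"pchip"` or `"makima"`.
#' @param anti_alias optional Butterworth pre-filter when down-sampling.
#' @return the resampled [uniform_series()] at `new_fs`.
#' @export
resample_series <- function(series, new_fs,
                            method = c("linear", "spline", "pchip",
                                       "makima"),
                            anti_alias = FALSE) {
  stopifnot(inherits(series, "uniform_series"))
  if (!is.numeric(new_fs) || new_fs <= 0)
    stop("new_fs must be > 0", call. = FALSE)
  method <- match.arg(method)
  if (anti_alias && new_fs < series$fs)
    series <- apply_filter(series, "butterworth",
                           cutoff = 0.45 * new_fs, order = 4, type = "low")
  v <- value_matrix(series)
  n <- nrow(v)
  if (n == 0L) { series$fs <- new_fs; return(series) }
  t_old <- (seq_len(n) - 1) / series$fs
  n_new <- floor((n - 1) * new_fs / series$fs) + 1
  t_new <- (seq_len(n_new) - 1) / new_fs
  out <- matrix(NaN, n_new, ncol(v))
  eps <- 1e-9
  for (ch in seq_len(ncol(v))) {
    runs <- finite_runs(v[, ch])
    for (r in seq_len(nrow(runs))) {
      i0 <- runs[r, 1]; i1 <- runs[r, 2]
      sel <- t_new >= t_old[i0] - eps & t_new <= t_old[i1] + eps
      if (!any(sel)) next
      out[sel, ch] <- interp_core(t_old[i0:i1], v[i0:i1, ch], t_new[sel],
                                  method)
    }
  }
  res <- set_values(series, out)
  res$fs <- new_fs
  res
}

#' Detrend a uniform series
#'
#' Three methods: `"linear"` subtracts a least-squares line; `"robust"` is
#' an iterative weighted polynomial fit in which samples whose residual
#' exceeds `thresh_sd` residual standard deviations are excluded from the
#' next pass; `"smoothness_priors"` estimates a slowly varying trend as the
#' solution of `(I + lambda^2 D2'D2) trend = z` with `D2` the second
#' difference operator, and returns `z - trend` (the classical
#' regularised-least-squares detrender used for heart-rate-variability
#' series; larger `lambda` removes only slower trends). `NaN` samples are
#' excluded from the fits and stay `NaN` in the output.
#'
#' @param series a [uniform_series()].
#' @param method `"linear"`, `"robust"` or `"smoothness_priors"`.
#' @param lambda smoothness parameter (> 0), `smoothness_priors` only.
#' @param order polynomial order (>= 0), `robust` only.
#' @param thresh_sd outlier threshold in residual SDs (> 0), `robust` only.
#' @param iters number of reweighting passes (>= 1), `robust` only.
#' @return the detrended [uniform_series()].
#' @export
detrend_series <- function(series,
                           method = c("linear", "robust",
                                      "smoothness_priors"),
                           lambda = 500, order = 3, thresh_sd = 3,
                           iters = 3) {
  stopifnot(inherits(series, "uniform_series"))
  method <- match.arg(method)
  if (method == "smoothness_priors" && (!is.numeric(lambda) || lambda <= 0))
    stop("lambda must be > 0", call. = FALSE)
  if (method == "robust" && (order < 0 || thresh_sd <= 0 || iters < 1))
    stop("robust detrend needs order >= 0, thresh_sd > 0, iters >= 1",
         call. = FALSE)
  v <- value_matrix(series)
  out <- v
  for (ch in seq_len(ncol(v))) {
    z <- v[, ch]
    ok <- is.finite(z)
    nf <- sum(ok)
    if (nf == 0L) next
    tt <- which(ok)
    if (method == "linear") {
      if (nf < 2L) { out[ok, ch] <- 0; next }
      fit <- stats::lm.fit(cbind(1, tt), z[ok])
      out[ok, ch] <- fit$residuals
    } else if (method == "smoothness_priors") {
      if (nf < 3L)
        stop("smoothness_priors needs at least 3 finite samples",
             call. = FALSE)
      out[ok, ch] <- z[ok] - sp_trend(z[ok], lambda)
    } else {  # robust
      deg <- min(order, nf - 1L)
      X <- if (deg == 0L) matrix(1, nf, 1L) else
        cbind(1, stats::poly(as.numeric(tt), degree = deg))
      w <- rep(1, nf)
      zz <- z[ok]
      for (it in seq_len(iters)) {
        fit <- stats::lm.wfit(X, zz, w)
        r <- as.numeric(zz - X %*% fit$coefficients)
        s <- stats::sd(r[w > 0])
        if (!is.finite(s) || s == 0) break
        w <- ifelse(abs(r) > thresh_sd * s, 0, 1)
        if (all(w == 0)) { w <- rep(1, nf); break }
      }
      out[ok, ch] <- zz - X %*% fit$coefficients
    }
  }
  set_values(series, out)
}

# smoothness-priors trend via sparse banded solve
sp_trend <- function(z, lambda) {
  n <- length(z)
  D <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                          diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                           rep(1, n - 2L)))
  A <- Matrix::Diagonal(n) + lambda^2 * Matrix::crossprod(D)
  as.numeric(Matrix::solve(A, z))
}

#' Filter a uniform series
#'
#' Moving mean and moving median use centred windows of odd sample length
#' (derived from `window_s`), truncated at the series edges. The
#' Butterworth filter is applied forward-backward (zero phase, doubling the
#' effective order). `NaN` runs propagate: each finite run is filtered on
#' its own.
#'
#' @param series a [uniform_series()].
#' @param kind `"movmean"`, `"movmedian"` or `"butterworth"`.
#' @param window_s moving-window length in seconds (moving filters).
#' @param cutoff cutoff frequency in Hz, or `c(low, high)` for band
#'   filters; must lie below the Nyquist frequency.
#' @param order Butterworth order (before the forward-backward doubling).
#' @param type Butterworth response: `"low"`, `"high"`, `"pass"`, `"stop"`.
#' @return the filtered [uniform_series()].
#' @export
apply_filter <- function(series,
                         kind = c("movmean", "movmedian", "butterworth"),
                         window_s = 1, cutoff = NULL, order = 4,
                         type = c("low", "high", "pass", "stop")) {
  stopifnot(inherits(series, "uniform_series"))
  kind <- match.arg(kind)
  v <- value_matrix(series)
  out <- v
  if (kind %in% c("movmean", "movmedian")) {
    w <- max(1L, round(window_s * series$fs))
    if (w %% 2L == 0L) w <- w + 1L
    for (ch in seq_len(ncol(v))) {
      runs <- finite_runs(v[, ch])
      for (r in seq_len(nrow(runs))) {
        i0 <- runs[r, 1]; i1 <- runs[r, 2]
        out[i0:i1, ch] <- moving_stat(v[i0:i1, ch], w, kind)
      }
    }
  } else {
    type <- match.arg(type)
    nyq <- series$fs / 2
    if (is.null(cutoff) || any(cutoff <= 0) || any(cutoff >= nyq))
      stop("butterworth cutoff must satisfy 0 < cutoff < fs/2 (Nyquist ",
           nyq, " Hz)", call. = FALSE)
    bf <- signal::butter(order, cutoff / nyq, type)
    for (ch in seq_len(ncol(v))) {
      runs <- finite_runs(v[, ch])
      for (r in seq_len(nrow(runs))) {
        i0 <- runs[r, 1]; i1 <- runs[r, 2]
        seg <- v[i0:i1, ch]
        res <- tryCatch(signal::filtfilt(bf, seg), error = function(e) NULL)
        if (is.null(res)) {
          warning("segment of ", length(seg),
                  " samples too short for zero-phase filtering; ",
                  "left unfiltered", call. = FALSE)
          res <- seg
        }
        out[i0:i1, ch] <- res
      }
    }
  }
  set_values(series, out)
}

# centred moving mean/median with truncated edge windows
moving_stat <- function(x, w, kind) {
  n <- length(x)
  half <- (w - 1L) %/% 2L
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  if (kind == "movmean") {
    cs <- cumsum(c(0, x))
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  } else {
    if (n >= w) {
      out <- as.numeric(stats::runmed(x, w, endrule = "keep"))
      edge <- c(seq_len(min(half, n)),
                seq.int(max(1L, n - half + 1L), n))
      for (i in unique(edge)) out[i] <- stats::median(x[lo[i]:hi[i]])
      out
    } else {
      vapply(seq_len(n), function(i) stats::median(x[lo[i]:hi[i]]), 0)
    }
  }
}

#' Artifact criteria
#'
#' Thresholds on the statistical properties of a signal. `amplitude` flags
#' individual samples outside `c(min, max)`; `zscore` flags samples whose
#' global z-score magnitude exceeds the threshold; `variance` and `sd` flag
#' every sample of a sliding window whose statistic exceeds the threshold;
#' `slope` flags adjacent-sample pairs whose absolute slope (units/second)
#' exceeds the threshold. Padding widens every detection by `pad_s` seconds
#' on both sides.
#'
#' @param amplitude `c(min, max)` or `NULL`.
#' @param zscore,variance,sd,slope single thresholds or `NULL`.
#' @param window_s sliding-window length (s) for `variance`/`sd`.
#' @param step_s window step (s); default one sample.
#' @param pad_s padding (s) added around detections.
#' @return object of class `artifact_criteria`.
#' @export
artifact_criteria <- function(amplitude = NULL, zscore = NULL,
                              variance = NULL, sd = NULL, slope = NULL,
                              window_s = 5, step_s = NULL, pad_s = 0) {
  if (is.null(amplitude) && is.null(zscore) && is.null(variance) &&
      is.null(sd) && is.null(slope))
    stop("no artifact criterion enabled", call. = FALSE)
  if (!is.null(amplitude) && length(amplitude) != 2L)
    stop("amplitude criterion needs c(min, max)", call. = FALSE)
  structure(list(amplitude = amplitude, zscore = zscore,
                 variance = variance, sd = sd, slope = slope,
                 window_s = window_s, step_s = step_s, pad_s = pad_s),
            class = "artifact_criteria")
}

#' Detect artifacts in a uniform series
#'
#' Applies every enabled criterion of an [artifact_criteria()], unions the
#' flagged samples (any channel), pads, and merges into sorted
#' non-overlapping segments.
#'
#' @param series a [uniform_series()].
#' @param criteria an [artifact_criteria()].
#' @return data.frame of class `artifact_segments` with 1-based inclusive
#'   `first`/`last` sample indices and the originating `criterion` label(s).
#' @export
detect_artifacts <- function(series, criteria) {
  stopifnot(inherits(series, "uniform_series"),
            inherits(criteria, "artifact_criteria"))
  v <- value_matrix(series)
  n <- nrow(v)
  fs <- series$fs
  flags <- list()
  flag0 <- rep(FALSE, n)
  if (!is.null(criteria$amplitude)) {
    f <- flag0
    for (ch in seq_len(ncol(v)))
      f <- f | (is.finite(v[, ch]) &
                  (v[, ch] < criteria$amplitude[1] |
                     v[, ch] > criteria$amplitude[2]))
    flags$amplitude <- f
  }
  if (!is.null(criteria$zscore)) {
    f <- flag0
    for (ch in seq_len(ncol(v))) {
      x <- v[, ch]
      mu <- mean(x[is.finite(x)])
      s <- stats::sd(x[is.finite(x)])
      if (is.finite(s) && s > 0)
        f <- f | (is.finite(x) & abs(x - mu) / s > criteria$zscore)
    }
    flags$zscore <- f
  }
  for (crit in c("variance", "sd")) {
    thr <- criteria[[crit]]
    if (is.null(thr)) next
    win <- max(2L, round(criteria$window_s * fs))
    if (criteria$window_s * fs < 2)
      stop("variance/sd criteria need window_s * fs >= 2", call. = FALSE)
    step <- max(1L, round((criteria$step_s %||% (1 / fs)) * fs))
    f <- flag0
    starts <- seq.int(1L, n, by = step)
    for (ch in seq_len(ncol(v))) {
      x <- v[, ch]
      for (s0 in starts) {
        s1 <- min(n, s0 + win - 1L)
        xs <- x[s0:s1]
        xs <- xs[is.finite(xs)]
        if (length(xs) < 2L) next
        stat <- if (crit == "variance") stats::var(xs) else stats::sd(xs)
        if (stat > thr) f[s0:s1] <- TRUE
      }
    }
    flags[[crit]] <- f
  }
  if (!is.null(criteria$slope)) {
    f <- flag0
    for (ch in seq_len(ncol(v))) {
      x <- v[, ch]
      pair <- is.finite(x[-n]) & is.finite(x[-1]) &
        abs(diff(x)) * fs > criteria$slope
      f[-n] <- f[-n] | pair
      f[-1] <- f[-1] | pair
    }
    flags$slope <- f
  }
  pad <- round(criteria$pad_s * fs)
  segs <- list()
  any_flag <- Reduce(`|`, flags, flag0)
  if (any(any_flag)) {
    r <- rle(any_flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    first <- pmax(1L, starts[r$values] - pad)
    last <- pmin(n, ends[r$values] + pad)
    # merge after padding
    keep_first <- numeric(0); keep_last <- numeric(0)
    for (i in seq_along(first)) {
      if (length(keep_first) && first[i] <= keep_last[length(keep_last)] + 1L) {
        keep_last[length(keep_last)] <- max(keep_last[length(keep_last)],
                                            last[i])
      } else {
        keep_first <- c(keep_first, first[i])
        keep_last <- c(keep_last, last[i])
      }
    }
    lab <- vapply(seq_along(keep_first), function(i) {
      hit <- vapply(names(flags), function(nm)
        any(flags[[nm]][keep_first[i]:keep_last[i]]), TRUE)
      paste(names(flags)[hit], collapse = "+")
    }, "")
    segs <- data.frame(first = keep_first, last = keep_last,
                       criterion = lab, stringsAsFactors = FALSE)
  } else {
    segs <- data.frame(first = numeric(0), last = numeric(0),
                       criterion = character(0), stringsAsFactors = FALSE)
  }
  attr(segs, "n") <- n
  class(segs) <- c("artifact_segments", "data.frame")
  segs
}

#' Reject detected artifact segments
#'
#' Flagged samples are set to `NaN`; everything else is untouched. The
#' applied segment list is recorded in the series' provenance attribute.
#'
#' @param series a [uniform_series()].
#' @param segments an `artifact_segments` data.frame from
#'   [detect_artifacts()].
#' @return the censored [uniform_series()].
#' @export
apply_artifacts <- function(series, segments) {
  stopifnot(inherits(series, "uniform_series"))
  v <- value_matrix(series)
  for (i in seq_len(nrow(segments)))
    v[segments$first[i]:segments$last[i], ] <- NaN
  out <- set_values(series, v)
  attr(out, "artifacts") <- c(attr(series, "artifacts"), list(segments))
  out
}

#' Fill missing-data gaps
#'
#' `NaN` runs no longer than `max_gap_s` are replaced: `previous`/`next`/
#' `nearest` copy neighbouring scores (the only methods that can fill
#' leading/trailing gaps); `linear`/`spline`/`pchip`/`makima` interpolate
#' from the finite samples; `movmean`/`movmedian` use the centred
#' moving-window statistic of the finite samples (window `window_s`).
#'
#' @param series a [uniform_series()].
#' @param method gap-filling method (see above).
#' @param max_gap_s only fill runs up to this many seconds (default: all).
#' @param window_s window length for the moving-statistic methods.
#' @return the gap-filled [uniform_series()].
#' @export
fill_gaps <- function(series,
                      method = c("previous", "next", "nearest", "linear",
                                 "spline", "pchip", "makima", "movmean",
                                 "movmedian"),
                      max_gap_s = Inf, window_s = 10) {
  stopifnot(inherits(series, "uniform_series"))
  method <- match.arg(method)
  v <- value_matrix(series)
  n <- nrow(v)
  if (n == 0L || !any(is.finite(v)))
    stop("no finite samples to fill from", call. = FALSE)
  max_run <- max_gap_s * series$fs + 0.5
  for (ch in seq_len(ncol(v))) {
    x <- v[, ch]
    bad <- !is.finite(x)
    if (!any(bad) || all(bad)) next
    r <- rle(bad)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gi <- which(r$values)
    for (g in gi) {
      i0 <- starts[g]; i1 <- ends[g]
      if (i1 - i0 + 1L > max_run) next
      prev_i <- if (i0 > 1L) i0 - 1L else NA_integer_
      next_i <- if (i1 < n) i1 + 1L else NA_integer_
      idx <- i0:i1
      fillv <- switch(method,
        previous = if (!is.na(prev_i)) rep(x[prev_i], length(idx)),
        `next` = if (!is.na(next_i)) rep(x[next_i], length(idx)),
        nearest = {
          if (is.na(prev_i) && is.na(next_i)) NULL
          else if (is.na(prev_i)) rep(x[next_i], length(idx))
          else if (is.na(next_i)) rep(x[prev_i], length(idx))
          else ifelse(idx - prev_i <= next_i - idx, x[prev_i], x[next_i])
        },
        movmean = , movmedian = {
          w <- max(1L, round(window_s * series$fs))
          half <- (if (w %% 2L == 0L) w else w - 1L) %/% 2L
          vapply(idx, function(i) {
            xs <- x[max(1L, i - half):min(n, i + half)]
            xs <- xs[is.finite(xs)]
            if (!length(xs)) NaN
            else if (method == "movmean") mean(xs) else stats::median(xs)
          }, 0)
        },
        {  # interpolating methods: interior gaps only
          if (is.na(prev_i) || is.na(next_i)) NULL
          else {
            fi <- which(is.finite(x))
            interp_core(fi, x[fi], idx, method)
          }
        })
      if (!is.null(fillv)) x[idx] <- fillv
    }
    v[, ch] <- x
  }
  set_values(series, v)
}

#' z-score transform
#'
#' Global mode standardises each channel by the mean and SD of its finite
#' samples; windowed mode standardises each sample by the statistics of a
#' centred window (truncated at the edges). `NaN` samples are preserved.
#'
#' @param series a [uniform_series()].
#' @param window_s window length in seconds, or `NULL` for the whole
#'   recording.
#' @return the transformed [uniform_series()].
#' @export
zscore_transform <- function(series, window_s = NULL) {
  stopifnot(inherits(series, "uniform_series"))
  v <- value_matrix(series)
  n <- nrow(v)
  out <- v
  for (ch in seq_len(ncol(v))) {
    x <- v[, ch]
    ok <- is.finite(x)
    if (!any(ok)) next
    if (is.null(window_s)) {
      s <- stats::sd(x[ok])
      if (!is.finite(s) || s == 0)
        stop("no variance: cannot z-score a constant series", call. = FALSE)
      out[ok, ch] <- (x[ok] - mean(x[ok])) / s
    } else {
      w <- max(2L, round(window_s * series$fs))
      half <- (if (w %% 2L == 0L) w + 1L else w) %/% 2L
      x0 <- ifelse(ok, x, 0)
      cs <- cumsum(c(0, x0))
      cs2 <- cumsum(c(0, x0^2))
      cn <- cumsum(c(0, as.numeric(ok)))
      lo <- pmax(1L, seq_len(n) - half)
      hi <- pmin(n, seq_len(n) + half)
      cnt <- cn[hi + 1L] - cn[lo]
      mu <- (cs[hi + 1L] - cs[lo]) / cnt
      ss <- (cs2[hi + 1L] - cs2[lo]) - cnt * mu^2
      sdw <- sqrt(pmax(ss, 0) / pmax(cnt - 1, 1))
      z <- (x - mu) / sdw
      z[!ok | cnt < 2 | sdw == 0] <- NaN
      out[, ch] <- z
    }
  }
  set_values(series, out)
}

#' Apply a preprocessing operation across a recording
#'
#' Runs the operation on every segment of every uniform modality in the
#' recording, and never on event series (systolic peaks are exempt from
#' resampling and every other preprocessing operation).
#'
#' @param rec a [recording()].
#' @param fun a function taking and returning a [uniform_series()] (e.g.
#'   `function(s) resample_series(s, 32)`).
#' @return the recording with every uniform series transformed.
#' @export
preprocess_all <- function(rec, fun) {
  stopifnot(inherits(rec, "recording"), is.function(fun))
  for (m in names(rec$dat)) {
    if (inherits(rec$dat[[m]], "event_series")) next
    rec$dat[[m]] <- lapply(rec$dat[[m]], fun)
  }
  rec
}
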