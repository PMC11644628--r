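# Preprocessing: oracles and contracts for every operation.

us <- function(v, fs = 4, mod = "EDA") uniform_series(mod, 0, fs, v)

test_that("every op preserves length, start and rate", {
  set.seed(1)
  v <- rnorm(400); v[50:60] <- NaN
  s <- us(v)
  ops <- list(
    function(x) detrend_series(x, "linear"),
    function(x) detrend_series(x, "smoothness_priors", lambda = 100),
    function(x) detrend_series(x, "robust", order = 2),
    function(x) apply_filter(x, "movmean", window_s = 1),
    function(x) apply_filter(x, "movmedian", window_s = 1),
    function(x) apply_filter(x, "butterworth", cutoff = 1),
    function(x) fill_gaps(x, "linear"),
    function(x) zscore_transform(x),
    function(x) zscore_transform(x, window_s = 10))
  for (f in ops) {
    out <- f(s)
    expect_equal(wristflow:::n_samples(out), 400)
    expect_equal(out$start_us, 0)
    expect_equal(out$fs, 4)
  }
  # NaN runs stay NaN through every non-filling op
  for (f in ops[-7])
    expect_true(all(is.nan(f(s)$values[50:60])))
})

test_that("resampling preserves constants, analytic sines and gaps", {
  const <- resample_series(us(rep(2.5, 40)), 8)
  expect_true(all(const$values == 2.5))
  expect_equal(const$fs, 8)

  fs <- 64
  t <- (0:(fs * 30 - 1)) / fs
  s <- uniform_series("BVP", 0, fs, sin(2 * pi * t))
  for (m in c("linear", "spline", "pchip", "makima")) {
    r <- resample_series(s, 32, m)
    tn <- (seq_len(wristflow:::n_samples(r)) - 1) / 32
    expect_lt(max(abs(r$values - sin(2 * pi * tn))), 1e-3, label = m)
  }
  # upsampling between grid points too
  r2 <- resample_series(s, 96, "spline")
  tn <- (seq_len(wristflow:::n_samples(r2)) - 1) / 96
  expect_lt(max(abs(r2$values - sin(2 * pi * tn))), 1e-3)

  # a NaN gap survives at the new rate, and is never bridged
  v <- sin(2 * pi * t); v[200:400] <- NaN
  r3 <- resample_series(uniform_series("BVP", 0, fs, v), 32, "pchip")
  gap_lo <- ceiling((199 / fs) * 32) + 1
  gap_hi <- floor((401 / fs) * 32)
  expect_true(all(is.nan(r3$values[(gap_lo + 1):gap_hi])))
  expect_error(resample_series(s, 0), "new_fs")
})

test_that("resampling extends to apply-to-all but never event series", {
  spec <- full_spec(duration_h = 0.1)
  fx <- write_fixture(spec)
  cfg <- read_config(fx$root, timezone = "Asia/Singapore")
  rec <- reconstitute(cfg)[[1]]
  n_pk <- length(rec$dat$SystP$times_ns)
  rec2 <- preprocess_all(rec, function(s) resample_series(s, 16))
  for (m in c("EDA", "BVP", "Temp", "ACC"))
    expect_equal(rec2$dat[[m]][[1]]$fs, 16, info = m)
  expect_identical(rec2$dat$SystP$times_ns, rec$dat$SystP$times_ns)
  expect_length(rec2$dat$SystP$times_ns, n_pk)
})

test_that("linear detrend annihilates an exact line", {
  tt <- 0:199
  s <- us(3 + 0.25 * tt)
  expect_lt(max(abs(detrend_series(s, "linear")$values)),
            1e-9 * 0.25 * 200)
})

test_that("smoothness-priors matches the dense solve and its limits", {
  set.seed(7)
  n <- 1500
  tt <- seq_len(n)
  x <- 0.5 + 0.002 * tt + sin(2 * pi * tt / 120) + rnorm(n, 0, 0.05)
  s <- us(x)
  lam <- 500
  # dense direct-solve oracle
  D <- diff(diag(n), differences = 2)
  trend <- solve(diag(n) + lam^2 * crossprod(D), x)
  got <- detrend_series(s, "smoothness_priors", lambda = lam)
  expect_lt(max(abs(got$values - (x - trend))), 1e-8)
  # lambda -> 0: (I + 0)^-1 = I, so the residual is the zero vector
  expect_lt(max(abs(detrend_series(s, "smoothness_priors",
                                   lambda = 1e-8)$values)), 1e-10)
  # lambda -> large on line+sine: equals linear detrend within 1% of the
  # oscillation amplitude
  x2 <- 1 + 0.01 * tt + sin(2 * pi * tt / 100)
  s2 <- us(x2)
  big <- detrend_series(s2, "smoothness_priors", lambda = 1e6)
  lin <- detrend_series(s2, "linear")
  expect_lt(max(abs(big$values - lin$values)), 0.01)
  expect_error(detrend_series(s, "smoothness_priors", lambda = 0),
               "lambda")
})

test_that("robust detrend ignores a huge spike on a parabola", {
  tt <- seq(-1, 1, length.out = 201)
  base <- 2 + tt + 3 * tt^2
  spiked <- base
  spiked[100] <- spiked[100] + 100
  got <- detrend_series(us(spiked), "robust", order = 2, thresh_sd = 3,
                        iters = 3)
  clean <- detrend_series(us(base), "robust", order = 2, thresh_sd = 3,
                          iters = 3)
  expect_lt(max(abs(got$values[-100] - clean$values[-100])), 1e-6)
  expect_gt(got$values[100], 50)  # the spike itself stays in the residual
})

test_that("moving filters match a brute-force per-window oracle", {
  set.seed(123)
  for (i in 1:1000) {
    n <- sample(4:50, 1)
    w <- sample(c(3, 5, 7, 9, 11), 1)
    x <- rnorm(n)
    half <- (w - 1) / 2
    lo <- pmax(1, seq_len(n) - half)
    hi <- pmin(n, seq_len(n) + half)
    want_mean <- vapply(seq_len(n), function(j) mean(x[lo[j]:hi[j]]), 0)
    want_med <- vapply(seq_len(n), function(j) median(x[lo[j]:hi[j]]), 0)
    s <- us(x, fs = 1)
    expect_equal(apply_filter(s, "movmean", window_s = w)$values,
                 want_mean, tolerance = 1e-12)
    expect_equal(apply_filter(s, "movmedian", window_s = w)$values,
                 want_med, tolerance = 1e-12)
  }
})

test_that("movmean agrees with the worked 5-sample example", {
  expect_equal(apply_filter(us(c(1, 2, 3, 4, 5), fs = 1), "movmean",
                            window_s = 3)$values,
               c(1.5, 2, 3, 4, 4.5))
})

test_that("butterworth is zero-phase and meets the attenuation contract", {
  fs <- 64
  t <- (0:(fs * 60 - 1)) / fs
  x <- sin(2 * pi * 0.1 * t) + sin(2 * pi * 10 * t)
  s <- uniform_series("BVP", 0, fs, x)
  f <- apply_filter(s, "butterworth", cutoff = 1, order = 4, type = "low")
  amp <- function(v, fr) {
    n <- length(v)
    2 * abs(fft(v)[round(fr * n / fs) + 1]) / n
  }
  expect_lt(20 * log10(amp(f$values, 10) / amp(x, 10)), -40)
  expect_lt(abs(amp(f$values, 0.1) / amp(x, 0.1) - 1), 0.01)
  # zero phase: peak of the passband component is not shifted
  slow <- sin(2 * pi * 0.1 * t)
  expect_lt(abs(which.max(f$values[1:640]) - which.max(slow[1:640])), 3)
  expect_error(apply_filter(s, "butterworth", cutoff = 40), "Nyquist")
})

test_that("artifact detection meets its recall and false-positive contract", {
  set.seed(42)
  n <- 8000
  x <- rnorm(n)
  s0 <- us(x)
  crit <- artifact_criteria(zscore = 5)
  # clean generator at default thresholds: no flags at all
  clean <- detect_artifacts(s0, crit)
  flagged0 <- sum(clean$last - clean$first + 1)
  expect_lt(flagged0 / n, 0.01)
  # spikes at >= 2x the threshold: recall 1.0
  spots <- c(500, 2000, 2002, 5500, 7999)
  x2 <- x
  x2[spots] <- 10 * sd(x)  # 2x the 5-SD threshold
  segs <- detect_artifacts(us(x2), crit)
  hit <- vapply(spots, function(i) any(segs$first <= i & segs$last >= i),
                TRUE)
  expect_true(all(hit))
  flagged <- sum(segs$last - segs$first + 1)
  expect_lt((flagged - length(spots)) / n, 0.01)
})

test_that("steps at twice the slope threshold are recovered", {
  set.seed(6)
  n <- 4000
  fs <- 4
  x <- rnorm(n, 0, 0.05)
  x[2000:n] <- x[2000:n] + 5  # step of 5 units in one sample period
  # threshold at half the injected step slope
  segs <- detect_artifacts(us(x, fs = fs),
                           artifact_criteria(slope = 5 * fs / 2))
  expect_true(any(segs$first <= 2000 & segs$last >= 2000))
})

test_that("constant series trigger no artifact criteria", {
  s <- us(rep(3, 500))
  crit <- artifact_criteria(zscore = 2, variance = 0.1, sd = 0.1,
                            slope = 0.1, window_s = 5)
  expect_equal(nrow(detect_artifacts(s, crit)), 0)
  expect_error(artifact_criteria(), "no artifact criterion")
})

test_that("padding merges nearby detections into one segment", {
  x <- rnorm(200, 0, 0.01)
  x[c(100, 103)] <- 5
  segs <- detect_artifacts(us(x), artifact_criteria(amplitude = c(-1, 1),
                                                    pad_s = 0.5))
  # pad of 2 samples at 4 Hz bridges the 3-sample gap
  expect_equal(nrow(segs), 1)
  expect_lte(segs$first, 98)
  expect_gte(segs$last, 105)
})

test_that("variance windows flag whole windows above threshold", {
  set.seed(10)
  x <- rnorm(1000, 0, 0.01)
  x[401:440] <- rnorm(40, 0, 2)  # 10-s burst of high variance at 4 Hz
  segs <- detect_artifacts(us(x), artifact_criteria(variance = 0.25,
                                                    window_s = 5))
  expect_true(any(segs$first <= 401 & segs$last >= 440))
  expect_match(segs$criterion[1], "variance")
})

test_that("applying artifacts censors exactly the flagged samples", {
  set.seed(2)
  s <- us(rnorm(1000))
  win <- c(0, 1000 / 4 * 1e6)
  before <- summarize_missing(s, win)
  empty <- detect_artifacts(s, artifact_criteria(zscore = 50))
  expect_identical(apply_artifacts(s, empty)$values, s$values)
  segs <- data.frame(first = c(11, 101), last = c(20, 150),
                     criterion = "manual")
  out <- apply_artifacts(s, segs)
  expect_true(all(is.nan(out$values[c(11:20, 101:150)])))
  expect_identical(out$values[-c(11:20, 101:150)],
                   s$values[-c(11:20, 101:150)])
  after <- summarize_missing(out, win)
  expect_equal(after$pct_missing - before$pct_missing, 100 * 60 / 1000)
  # full-range segment: everything NaN
  allseg <- data.frame(first = 1, last = 1000, criterion = "manual")
  expect_true(all(is.nan(apply_artifacts(s, allseg)$values)))
})

test_that("gap filling follows each method's contract", {
  expect_equal(fill_gaps(us(c(1, NaN, 3), fs = 1), "linear")$values,
               c(1, 2, 3))
  expect_equal(fill_gaps(us(c(1, NaN, NaN, 4), fs = 1), "previous")$values,
               c(1, 1, 1, 4))
  expect_equal(fill_gaps(us(c(1, NaN, NaN, 4), fs = 1), "next")$values,
               c(1, 4, 4, 4))
  expect_equal(fill_gaps(us(c(1, NaN, NaN, 4), fs = 1), "nearest")$values,
               c(1, 1, 4, 4))
  # leading gaps only fill for next/nearest; interpolants leave them NaN
  expect_true(is.nan(fill_gaps(us(c(NaN, 2, 3), fs = 1),
                               "linear")$values[1]))
  expect_equal(fill_gaps(us(c(NaN, 2, 3), fs = 1), "next")$values[1], 2)
  # max_gap_s: long runs stay missing
  v <- c(1, NaN, 3, NaN, NaN, NaN, NaN, 8)
  out <- fill_gaps(us(v, fs = 1), "linear", max_gap_s = 2)
  expect_equal(out$values[2], 2)
  expect_true(all(is.nan(out$values[4:7])))
  expect_error(fill_gaps(us(rep(NaN, 5)), "linear"), "no finite samples")
})

test_that("pchip reconstructs a randomly punctured sine to within 5%", {
  set.seed(15)
  fs <- 8
  t <- (0:(fs * 120 - 1)) / fs
  truth <- sin(2 * pi * 0.05 * t)
  v <- truth
  v[sample(length(v), length(v) %/% 10)] <- NaN
  out <- fill_gaps(uniform_series("EDA", 0, fs, v), "pchip")
  expect_lt(sqrt(mean((out$values - truth)^2)), 0.05)
})

test_that("moving-window fills use neighbourhood statistics", {
  v <- c(1, 1, 1, NaN, 5, 5, 5)
  out <- fill_gaps(us(v, fs = 1), "movmean", window_s = 7)
  expect_equal(out$values[4], 3)
  out2 <- fill_gaps(us(v, fs = 1), "movmedian", window_s = 3)
  expect_equal(out2$values[4], 3)  # median of 1, 5
})

test_that("z-scoring is exact globally and locally on a slow ramp", {
  set.seed(3)
  s <- us(rnorm(2000, 10, 4))
  z <- zscore_transform(s)
  expect_lt(abs(mean(z$values)), 1e-9)
  expect_lt(abs(sd(z$values) - 1), 1e-9)
  expect_error(zscore_transform(us(rep(2, 50))), "no variance")
  # windowed oracle (brute force per sample)
  x <- s$values[1:300]
  sw <- zscore_transform(us(x), window_s = 5)  # 21-sample windows at 4 Hz
  half <- 10
  want <- vapply(seq_along(x), function(i) {
    xs <- x[max(1, i - half):min(length(x), i + half)]
    (x[i] - mean(xs)) / sd(xs)
  }, 0)
  expect_equal(sw$values, want, tolerance = 1e-9)
  # windowed z of a slow ramp is locally centred
  ramp <- us(seq(0, 10, length.out = 400))
  zr <- zscore_transform(ramp, window_s = 10)
  expect_lt(abs(mean(zr$values[50:350])), 0.05)
})

test_that("multi-channel accelerometry is processed per channel", {
  set.seed(8)
  m <- cbind(x = rnorm(200), y = rnorm(200, 5), z = rnorm(200, -3))
  s <- uniform_series("ACC", 0, 32, m)
  z <- zscore_transform(s)
  expect_equal(unname(colMeans(z$values)), c(0, 0, 0), tolerance = 1e-9)
  f <- apply_filter(s, "movmean", window_s = 5 / 32)
  expect_equal(ncol(f$values), 3)
})
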