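test_that("DTF of an identity transfer is the identity pattern", {
  tr <- transfer_matrix(bare_model(array(0, c(3, 3, 1))), seq(0, 64, 4))
  d <- dtf(tr)
  for (fi in seq_along(d$frequencies)) {
    expect_equal(d$values[, , fi], diag(3))
  }
  expect_true(d$directed)
  expect_equal(d$estimator, "DTF")
})

test_that("absent transfer paths give exactly zero DTF", {
  # coupling only 1 -> 2: the characteristic matrix is lower triangular at
  # every frequency, so H_12 = 0 and no inflow 2 -> 1 is reported
  A <- array(0, c(2, 2, 1))
  A[1, 1, 1] <- 0.5; A[2, 2, 1] <- 0.4; A[2, 1, 1] <- 0.6
  d <- dtf(transfer_matrix(bare_model(A)))
  expect_equal(max(abs(d$values[1, 2, ])), 0)
  expect_true(all(d$values[2, 1, ] > 0))
})

test_that("DTF matches an independent closed-form 2x2 inversion", {
  A <- array(0, c(2, 2, 2))
  A[, , 1] <- matrix(c(0.5, 0.0, 0.45, 0.4), 2, byrow = TRUE)
  A[, , 2] <- matrix(c(-0.3, 0.0, 0.1, -0.25), 2, byrow = TRUE)
  f <- seq(0, 64, by = 1)
  d <- dtf(transfer_matrix(bare_model(A), f))
  for (fi in seq_along(f)) {
    z1 <- exp(-2i * pi * f[fi] * 1 / 128)
    z2 <- exp(-2i * pi * f[fi] * 2 / 128)
    # 2x2 adjugate inverse, written out by hand
    a11 <- 1 - A[1, 1, 1] * z1 - A[1, 1, 2] * z2
    a12 <- -A[1, 2, 1] * z1 - A[1, 2, 2] * z2
    a21 <- -A[2, 1, 1] * z1 - A[2, 1, 2] * z2
    a22 <- 1 - A[2, 2, 1] * z1 - A[2, 2, 2] * z2
    det <- a11 * a22 - a12 * a21
    H <- matrix(c(a22, -a21, -a12, a11), 2) / det
    expect_equal(d$values[2, 1, fi],
                 abs(H[2, 1])^2 / (abs(H[2, 1])^2 + abs(H[2, 2])^2),
                 tolerance = 1e-12)
  }
})

test_that("DTF rows are normalized across fitted models", {
  for (seed in 1:4) {
    rec <- simulate_mvar_network(fixture_ar2_3ch()$A, fixture_ar2_3ch()$V,
                                 sim_config(n_samples = 1024,
                                            seed = seed))$recording
    d <- dtf(transfer_matrix(fit_mvar(rec, 2)))
    sums <- apply(d$values, c(1, 3), sum)
    expect_lt(max(abs(sums - 1)), 1e-9)
    expect_true(all(d$values >= 0 & d$values <= 1))
  }
})

test_that("coherence is unity on the diagonal and near-bias off it", {
  rec <- white_recording(2176, 2, seed = 21)   # 16 Hann segments at 50%
  ch <- coherence(rec)
  expect_equal(ch$n_segments, 16)
  expect_true(all(ch$values[1, 1, ] == 1))
  expect_false(ch$directed)
  # independent channels: mean coherence stays at the 1/n_segments bias scale
  expect_lt(mean(ch$values[1, 2, ]), 0.2)
  # symmetry
  expect_equal(ch$values[1, 2, ], ch$values[2, 1, ])
  expect_error(coherence(white_recording(300, 2, 1),
                         segment_length = 400), "segment_length")
})

test_that("common-signal coherence follows the closed form at the peak", {
  set.seed(31)
  fs <- 128; n <- 8192
  s <- gen_source_signal(n, fs, seed = 31)
  sigma <- 0.5
  x <- s + rnorm(n, sd = sigma)
  y <- s + rnorm(n, sd = sigma)
  rec <- recording(cbind(x, y), fs, c("a", "b"))
  ch <- coherence(rec)
  # oracle: P_s at the peak from the averaged periodogram of s alone,
  # flat noise density sigma^2 / fs; coh = (P_s / (P_s + P_n))^2
  seg <- 256
  nseg <- n %/% seg
  P <- 0
  for (k in seq_len(nseg)) {
    P <- P + abs(fft(s[((k - 1) * seg + 1):(k * seg)])[1:(seg / 2 + 1)])^2 /
      (seg * fs)
  }
  P <- P / nseg
  fgrid <- seq(0, fs / 2, length.out = seg / 2 + 1)
  peak <- which.max(P)
  pn <- sigma^2 / fs
  expected <- (P[peak] / (P[peak] + pn))^2
  expect_equal(ch$values[1, 2, peak], expected, tolerance = 0.05)
  expect_gt(fgrid[peak], 8); expect_lt(fgrid[peak], 13)
})

test_that("band integration averages the grid points in the closed band", {
  vals <- array(0.37, c(2, 2, 5))
  sp <- structure(list(values = vals, frequencies = c(2, 4, 6, 8, 10),
                       estimator = "DTF", directed = TRUE,
                       channel_labels = c("a", "b")),
                  class = "conn_spectrum")
  expect_equal(band_integrate(sp, 2, 10)$values,
               matrix(0.37, 2, 2, dimnames = list(c("a", "b"), c("a", "b"))))
  # single grid point
  sp$values[, , 3] <- 0.9
  expect_true(all(band_integrate(sp, 5.5, 6.5)$values == 0.9))
  expect_error(band_integrate(sp, 11, 12), "no grid point")
  expect_error(band_integrate(sp, 6, 6), "f_lo < f_hi")
})

test_that("conventional analysis bands integrate a fitted DTF", {
  rec <- simulate_common_source(2, c(2, 4),
                                sim_config(seed = 8))$recording
  d <- dtf(transfer_matrix(fit_mvar(rec, 8)))
  for (band in list(c(0.5, 40), c(1, 45), c(4, 60))) {
    ic <- band_integrate(d, band[1], band[2])
    expect_true(all(ic$values >= 0 & ic$values <= 1))
    expect_equal(ic$band, band)
  }
})

test_that("SDTF is flat on stationary ensembles and sees a coupling onset", {
  A <- array(c(0.5, 0.4, 0, 0.5), c(2, 2, 1))
  trials <- lapply(1:12, function(s) {
    simulate_mvar_network(A, diag(2),
                          sim_config(n_samples = 768, seed = s),
                          labels = c("a", "b"))$recording
  })
  res <- sdtf(trials, window_length = 128, step = 64, order = 2)
  v <- sapply(res$spectra, function(sp) band_integrate(sp, 1, 45)$values)
  expect_lt(max(apply(v, 1, sd)), 0.1)

  make_switch_trial <- function(seed, n = 768) {
    set.seed(seed)
    X <- matrix(0, n, 2); E <- matrix(rnorm(n * 2), n, 2)
    for (t in 2:n) {
      a21 <- if (t > n / 2) 0.6 else 0
      X[t, 1] <- 0.5 * X[t - 1, 1] + E[t, 1]
      X[t, 2] <- 0.5 * X[t - 1, 2] + a21 * X[t - 1, 1] + E[t, 2]
    }
    recording(X, 128, c("src", "dst"))
  }
  hits <- vapply(1:10, function(s) {
    trials <- lapply(s * 100 + 1:12, make_switch_trial)
    res <- sdtf(trials, window_length = 128, step = 64, order = 2)
    v <- vapply(res$spectra, function(sp) {
      mean(band_integrate(sp, 1, 45)$values[2, 1])
    }, numeric(1))
    pre <- v[res$window_start + 128 <= 384]
    post <- v[res$window_start >= 385]
    mean(post) > mean(pre)
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  expect_error(sdtf(trials[1:5], 128, 64, 2), "at least 10")
  expect_error(sdtf(trials, 6, 4, 6), "window_length")
  expect_error(sdtf(trials, 8, 4, 6), "under-determined")
})
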