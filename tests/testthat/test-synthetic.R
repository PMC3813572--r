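test_that("source surrogate is deterministic, high-passed and alpha-peaked", {
  s1 <- gen_source_signal(2560, 128, seed = 1)
  s2 <- gen_source_signal(2560, 128, seed = 1)
  expect_identical(s1, s2)
  expect_equal(mean(s1), 0, tolerance = 1e-12)
  expect_equal(sd(s1), 1, tolerance = 1e-12)

  # power below the 3 Hz high-pass corner is a sliver of the total
  pg <- Mod(fft(s1))^2
  f <- seq(0, 128, length.out = length(pg) + 1)[seq_along(pg)]
  half <- f <= 64
  expect_lt(sum(pg[half & f < 3]) / sum(pg[half]), 0.05)

  # spectral peak lands in the alpha band for every seed
  for (seed in 1:5) {
    s <- gen_source_signal(2560, 128, seed = seed)
    sp <- spec.pgram(ts(s, frequency = 128), spans = 9, plot = FALSE,
                     taper = 0, detrend = FALSE)
    expect_true(sp$freq[which.max(sp$spec)] >= 8 &&
                  sp$freq[which.max(sp$spec)] <= 13)
  }

  expect_error(gen_source_signal(100, 128, 1), "n_samples")
  expect_error(gen_source_signal(512, 10, 1), "sampling_rate")
})

test_that("common-source simulation has the stated structure and delays", {
  cfg <- sim_config(n_samples = 2560, snr = 4, seed = 3)
  sim <- simulate_common_source(4, c(2, 4, 6, 8), cfg)
  expect_s3_class(sim$recording, "mc_recording")
  expect_equal(n_channels(sim$recording), 5)
  expect_equal(nrow(sim$truth$edges), 4)
  expect_true(all(sim$truth$edges$source == sim$recording$channel_labels[1]))

  # determinism and the equal-variance contract
  sim2 <- simulate_common_source(4, c(2, 4, 6, 8), cfg)
  expect_identical(sim$recording$data, sim2$recording$data)
  v <- apply(sim$recording$data, 2, var)
  expect_lt(max(v) / min(v), 1.1)

  # brute-force cross-correlation over all lags peaks at the planted delay
  X <- sim$recording$data
  for (k in 1:4) {
    lags <- 0:12
    cc <- vapply(lags, function(L) {
      n <- nrow(X)
      cor(X[1:(n - L), 1], X[(1 + L):n, k + 1])
    }, numeric(1))
    expect_equal(lags[which.max(cc)], sim$truth$edges$delay[k])
  }
})

test_that("noiseless zero-delay sink duplicates the source channel", {
  sim <- simulate_common_source(1, 0L, sim_config(snr = 1e9, seed = 1))
  expect_equal(sim$recording$data[, 1], sim$recording$data[, 2],
               tolerance = 1e-6)
})

test_that("common-source rejects bad delays", {
  expect_error(simulate_common_source(2, c(1, 2600), sim_config()),
               "delay")
  expect_error(simulate_common_source(2, c(-1, 2), sim_config()),
               "non-negative")
  expect_error(simulate_common_source(2, 1L, sim_config()), "length")
})

test_that("MVAR simulation matches its stated system", {
  # null system: independent white channels
  A0 <- array(0, c(3, 3, 1))
  sim <- simulate_mvar_network(A0, diag(3), sim_config(n_samples = 4096,
                                                       seed = 2))
  expect_equal(nrow(sim$truth$edges), 0)
  cors <- cor(sim$recording$data)
  expect_lt(max(abs(cors[upper.tri(cors)])), 3 / sqrt(4096))

  # single planted coefficient -> single truth edge 1 -> 2
  A1 <- array(0, c(2, 2, 1)); A1[2, 1, 1] <- 0.5
  sim1 <- simulate_mvar_network(A1, diag(2), sim_config(seed = 1),
                                labels = c("a", "b"))
  expect_equal(sim1$truth$edges$source, "a")
  expect_equal(sim1$truth$edges$target, "b")

  # instability is refused
  Abad <- array(0, c(2, 2, 1)); diag(Abad[, , 1]) <- 1.05
  expect_error(simulate_mvar_network(Abad, diag(2), sim_config()),
               "unstable")
  expect_error(simulate_mvar_network(A1, matrix(c(1, 2, 2, 1), 2),
                                     sim_config()), "positive definite")
})

test_that("long MVAR realization matches the Lyapunov-equation covariance", {
  fx <- fixture_ar2_3ch()
  K <- 3; p <- 2
  # companion-form stationary covariance: vec(P) = (I - F (x) F)^-1 vec(Q)
  Fm <- matrix(0, K * p, K * p)
  Fm[1:K, 1:K] <- fx$A[, , 1]
  Fm[1:K, (K + 1):(2 * K)] <- fx$A[, , 2]
  Fm[(K + 1):(2 * K), 1:K] <- diag(K)
  Q <- matrix(0, K * p, K * p)
  Q[1:K, 1:K] <- fx$V
  vecP <- solve(diag((K * p)^2) - kronecker(Fm, Fm), as.vector(Q))
  P <- matrix(vecP, K * p)[1:K, 1:K]
  sim <- simulate_mvar_network(fx$A, fx$V,
                               sim_config(n_samples = 32768, seed = 4))
  S <- cov(sim$recording$data)
  # 5% relative to the covariance scale (entry-wise relative error is
  # meaningless for near-zero cross-covariances)
  expect_lt(max(abs(S - P)) / max(abs(P)), 0.05)
})

test_that("volume conduction mixes one source at zero lag", {
  # equal weights, effectively no noise: all channels identical
  rec <- simulate_volume_conduction(3, c(1, 1, 1),
                                    sim_config(snr = 1e9, seed = 1))
  expect_equal(rec$data[, 1], rec$data[, 2], tolerance = 1e-6)
  expect_equal(rec$data[, 1], rec$data[, 3], tolerance = 1e-6)

  # cross-spectrum phase ~ 0 and coherence ~ 1 in-band at high SNR
  rec <- simulate_volume_conduction(3, c(1, 0.7, 1.3),
                                    sim_config(snr = 20, seed = 2))
  seg <- 256; X <- rec$data; nseg <- nrow(X) %/% seg
  S12 <- 0i
  for (k in seq_len(nseg)) {
    Fm <- mvfft(X[((k - 1) * seg + 1):(k * seg), ])[1:(seg / 2 + 1), ]
    S12 <- S12 + Fm[, 1] * Conj(Fm[, 2])
  }
  f <- seq(0, 64, length.out = seg / 2 + 1)
  inband <- f >= 6 & f <= 14    # around the source peak, where SNR is high
  expect_lt(max(abs(Arg(S12[inband]))), 0.1)
  coh <- band_integrate(coherence(rec), 6, 14)$values
  expect_gt(min(coh[upper.tri(coh)]), 0.9)

  expect_error(simulate_volume_conduction(1, 1, sim_config()),
               "n_channels")
  expect_error(simulate_volume_conduction(2, c(1, -1), sim_config()),
               "positive")
})

test_that("modular networks honor the partition and gain ordering", {
  part <- module_partition(list(M1 = c("Fp1", "Fp2", "F3"),
                                M2 = c("C3", "C4", "Cz")))
  sim <- suppressMessages(
    simulate_modular_network(part, intra_gain = 0.2, inter_gain = 0,
                             config = sim_config(n_samples = 1024, seed = 1)))
  mod_of <- c(Fp1 = "M1", Fp2 = "M1", F3 = "M1",
              C3 = "M2", C4 = "M2", Cz = "M2")
  ed <- sim$truth$edges
  expect_true(all(mod_of[ed$source] == mod_of[ed$target]))
  expect_lt(sim$radius, 1)
  expect_error(simulate_modular_network(part, 0.1, 0.2, sim_config()),
               "intra_gain")
})

test_that("generator outputs satisfy the recording invariants", {
  for (seed in 1:3) {
    cfg <- sim_config(n_samples = 512 + 128 * seed, snr = 0.5 + seed,
                      seed = seed)
    recs <- list(
      simulate_common_source(3, c(1, 3, 5), cfg)$recording,
      simulate_volume_conduction(3, c(1, 2, 0.5), cfg),
      simulate_mvar_network(fixture_ar2_3ch()$A, fixture_ar2_3ch()$V,
                            cfg)$recording)
    for (r in recs) {
      expect_false(anyNA(r$data))
      expect_gte(n_channels(r), 2)
      expect_gt(n_samples(r), 10 * n_channels(r))
      expect_equal(length(unique(r$channel_labels)), n_channels(r))
    }
  }
})
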