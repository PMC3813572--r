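#' Simulation configuration
#'
#' Bundles the sample count, sampling rate, per-channel signal-to-noise ratio
#' and master seed shared by all synthetic generators. Identical
#' configurations (and generator arguments) always produce identical output.
#'
#' SNR is defined as RMS(signal) / RMS(additive noise) at each channel;
#' every channel receives noise from its own independent stream, sub-seeded
#' from the master seed.
#'
#' @param n_samples number of time samples (default 2560, i.e. 20 s at
#'   128 Hz — the resting-state fixture size).
#' @param sampling_rate sampling rate in Hz (default 128).
#' @param snr signal-to-noise ratio, positive (default 2).
#' @param seed integer master seed.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_samples = 2560, sampling_rate = 128, snr = 2,
                       seed = 1L) {
  if (n_samples < 256) stop_invalid("n_samples must be >= 256")
  if (sampling_rate <= 0) stop_invalid("sampling_rate must be positive")
  if (!is.numeric(snr) || snr <= 0) stop_invalid("snr must be > 0")
  structure(list(n_samples = as.integer(n_samples),
                 sampling_rate = sampling_rate, snr = snr,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Broadband EEG-like surrogate source signal
#'
#' A stable AR(4) process with a complex pole pair at 10 Hz (modulus 0.92)
#' giving an alpha-band spectral peak, high-pass filtered at 3 Hz
#' (4th-order Butterworth, zero-phase) and standardized to zero mean and unit
#' variance. Serves as the stand-in for the experimental EEG trace driving the
#' common-source and volume-conduction simulations.
#'
#' @param n_samples length of the series (>= 256).
#' @param sampling_rate sampling rate in Hz (> 26, so the 3 Hz high-pass and
#'   10 Hz peak are below Nyquist).
#' @param seed integer seed.
#' @return numeric vector of length `n_samples`.
#' @examples
#' s <- gen_source_signal(2560, 128, seed = 1)
#' c(mean(s), sd(s))
#' @export
gen_source_signal <- function(n_samples, sampling_rate, seed) {
  if (n_samples < 256) stop_invalid("n_samples must be >= 256")
  if (sampling_rate <= 26) stop_invalid("sampling_rate must exceed 26 Hz")
  # AR(4) as the product of two pole pairs: a sharp alpha resonance at
  # 10 Hz (modulus 0.92) and a weak damping pair at 20 Hz (modulus 0.3)
  quad <- function(r, f_hz) {
    c(1, -2 * r * cos(2 * pi * f_hz / sampling_rate), r^2)
  }
  char_poly <- convolve(quad(0.92, 10), rev(quad(0.3, 20)), type = "open")
  a <- -char_poly[-1]
  burn <- 500
  x <- with_seed(seed, stats::rnorm(n_samples + burn))
  x <- as.numeric(stats::filter(x, a, method = "recursive"))[-seq_len(burn)]
  hp <- signal::butter(4, 3 / (sampling_rate / 2), type = "high")
  x <- as.numeric(signal::filtfilt(hp, x))
  (x - mean(x)) / stats::sd(x)
}

#' Common-source propagation simulation
#'
#' One source channel drives `n_sinks` destination channels. Channel 1 is the
#' source signal plus measurement noise; each destination channel is the
#' *channel-1 signal* delayed by a per-channel integer lag with extra
#' independent noise added — the propagating quantity is the observed channel,
#' so the ground truth consists of exactly the `n_sinks` edges 1 -> k+1.
#' Channels are standardized to unit variance on output.
#'
#' @param n_sinks number of destination channels (>= 1).
#' @param delays integer vector of `n_sinks` non-negative sample delays,
#'   each < `n_samples`.
#' @param config a [sim_config()].
#' @param labels optional channel labels (default: first `n_sinks + 1`
#'   10-20 names).
#' @return list with elements `recording` ([recording()]) and
#'   `truth` ([ground_truth()]).
#' @examples
#' sim <- simulate_common_source(4, c(2, 4, 6, 8), sim_config(seed = 1))
#' sim$truth$edges
#' @export
simulate_common_source <- function(n_sinks, delays, config = sim_config(),
                                   labels = NULL) {
  if (n_sinks < 1) stop_invalid("n_sinks must be >= 1")
  delays <- as.integer(delays)
  if (length(delays) != n_sinks) {
    stop_invalid("'delays' must have length n_sinks")
  }
  if (any(delays < 0)) stop_invalid("delays must be non-negative")
  if (any(delays >= config$n_samples)) {
    stop_invalid("delay >= n_samples")
  }
  n <- config$n_samples
  D <- max(delays, 0L)
  if (is.null(labels)) labels <- montage_1020(n_sinks + 1)
  noise_sd <- 1 / config$snr
  src <- gen_source_signal(n + D, config$sampling_rate,
                           sub_seed(config$seed, 0L))
  # channel 1 over the extended support; the head max(delay) samples are
  # dropped from every channel so all share a valid support
  ch1 <- src + with_seed(sub_seed(config$seed, 1L),
                         stats::rnorm(n + D, sd = noise_sd))
  X <- matrix(0, n, n_sinks + 1)
  X[, 1] <- ch1[(D + 1):(D + n)]
  for (k in seq_len(n_sinks)) {
    d <- delays[k]
    extra <- with_seed(sub_seed(config$seed, k + 1L),
                       stats::rnorm(n, sd = noise_sd))
    X[, k + 1] <- ch1[(D + 1 - d):(D + n - d)] + extra
  }
  X <- sweep(sweep(X, 2, colMeans(X)), 2, apply(X, 2, stats::sd), "/")
  rec <- recording(X, config$sampling_rate, labels)
  edges <- data.frame(source = labels[1], target = labels[-1],
                      delay = delays, gain = 1)
  list(recording = rec,
       truth = ground_truth(edges, labels, source_channels = labels[1]))
}

# companion-matrix spectral radius of an MVAR coefficient array (K x K x p)
companion_radius <- function(A) {
  K <- dim(A)[1]; p <- dim(A)[3]
  Fm <- matrix(0, K * p, K * p)
  for (m in seq_len(p)) Fm[1:K, ((m - 1) * K + 1):(m * K)] <- A[, , m]
  if (p > 1) {
    Fm[(K + 1):(K * p), 1:(K * (p - 1))] <- diag(K * (p - 1))
  }
  max(Mod(eigen(Fm, only.values = TRUE)$values))
}

as_coef_array <- function(coefficients) {
  if (is.list(coefficients)) {
    coefficients <- array(unlist(coefficients),
                          dim = c(dim(coefficients[[1]]),
                                  length(coefficients)))
  }
  if (length(dim(coefficients)) == 2) {
    coefficients <- array(coefficients, dim = c(dim(coefficients), 1))
  }
  if (dim(coefficients)[1] != dim(coefficients)[2]) {
    stop_invalid("coefficient matrices must be square")
  }
  coefficients
}

#' Simulate a recording from a known MVAR system
#'
#' Generates data by the exact MVAR recursion
#' `x_t = sum_m A_m x_{t-m} + e_t` with Gaussian innovations of covariance
#' `noise_cov`, after discarding a burn-in of `10 * order * n_channels`
#' samples. The ground truth contains every directed pair (j -> i), i != j,
#' with a nonzero coefficient at any lag.
#'
#' @param coefficients array `K x K x p` (or list of p `K x K` matrices) of
#'   autoregressive coefficients; `coefficients[i, j, m]` couples channel j at
#'   lag m into channel i. The companion spectral radius must be < 1.
#' @param noise_cov symmetric positive-definite innovation covariance
#'   (default identity).
#' @param config a [sim_config()] (its `snr` is ignored here; noise enters
#'   through `noise_cov`).
#' @param labels optional channel labels.
#' @return list with `recording`, `truth` and the spectral `radius`.
#' @export
simulate_mvar_network <- function(coefficients, noise_cov = NULL,
                                  config = sim_config(), labels = NULL) {
  A <- as_coef_array(coefficients)
  K <- dim(A)[1]; p <- dim(A)[3]
  if (is.null(noise_cov)) noise_cov <- diag(K)
  if (!isSymmetric(unname(noise_cov))) {
    stop_invalid("noise_cov must be symmetric")
  }
  ev <- eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop_invalid("noise_cov must be positive definite")
  rho <- companion_radius(A)
  if (rho >= 1) {
    stop_invalid(sprintf(
      "unstable MVAR system: companion spectral radius %.3f >= 1", rho))
  }
  if (is.null(labels)) labels <- montage_1020(K)
  n <- config$n_samples
  burn <- 10L * p * K
  total <- n + burn
  L <- chol(noise_cov)  # upper triangular, t(L) %*% L... cov(Z %*% L) = L'L
  E <- with_seed(config$seed,
                 matrix(stats::rnorm(total * K), total, K)) %*% L
  X <- matrix(0, total, K)
  for (t in seq_len(total)) {
    acc <- E[t, ]
    for (m in seq_len(min(p, t - 1))) {
      acc <- acc + A[, , m] %*% X[t - m, ]
    }
    X[t, ] <- acc
  }
  X <- X[(burn + 1):total, , drop = FALSE]
  rec <- recording(X, config$sampling_rate, labels)
  idx <- which(apply(abs(A), c(1, 2), sum) > 0 & !diag(K), arr.ind = TRUE)
  edges <- if (nrow(idx)) {
    first_lag <- vapply(seq_len(nrow(idx)), function(r) {
      which(A[idx[r, 1], idx[r, 2], ] != 0)[1]
    }, integer(1))
    gain <- vapply(seq_len(nrow(idx)), function(r) {
      A[idx[r, 1], idx[r, 2], first_lag[r]]
    }, numeric(1))
    data.frame(source = labels[idx[, 2]], target = labels[idx[, 1]],
               delay = first_lag, gain = gain)
  } else {
    data.frame(source = character(), target = character(),
               delay = integer(), gain = numeric())
  }
  list(recording = rec, truth = ground_truth(edges, labels), radius = rho)
}

#' Instantaneous (zero-phase) mixing simulation
#'
#' Emulates volume conduction: every channel receives the *same* source at
#' zero lag, scaled by a positive weight, plus independent noise
#' (`sd = weight / snr`, keeping the per-channel SNR constant). There is no
#' propagation delay anywhere, hence no ground-truth causal edge. Channels
#' are standardized on output.
#'
#' @param n_channels number of channels (>= 2).
#' @param mixing_weights positive weights, one per channel (default all 1).
#' @param config a [sim_config()].
#' @param labels optional channel labels.
#' @return an [recording()] object.
#' @export
simulate_volume_conduction <- function(n_channels,
                                       mixing_weights = rep(1, n_channels),
                                       config = sim_config(), labels = NULL) {
  if (n_channels < 2) stop_invalid("n_channels must be >= 2")
  if (length(mixing_weights) != n_channels || any(mixing_weights <= 0)) {
    stop_invalid("mixing_weights must be ", n_channels, " positive numbers")
  }
  if (is.null(labels)) labels <- montage_1020(n_channels)
  n <- config$n_samples
  src <- gen_source_signal(n, config$sampling_rate, sub_seed(config$seed, 0L))
  X <- vapply(seq_len(n_channels), function(k) {
    mixing_weights[k] * src +
      with_seed(sub_seed(config$seed, k),
                stats::rnorm(n, sd = mixing_weights[k] / config$snr))
  }, numeric(n))
  sds <- apply(X, 2, stats::sd)
  X <- sweep(sweep(X, 2, colMeans(X)), 2, sds, "/")
  recording(X, config$sampling_rate, labels)
}

#' Modular directed network simulation
#'
#' Builds a stable MVAR system whose channels are grouped into modules with
#' dense intra-module directed coupling at `intra_gain` and sparse
#' inter-module coupling at `inter_gain`, then simulates a recording from it.
#' Each channel keeps mild private AR(2) dynamics. If the assembled system is
#' unstable, all cross-channel couplings are rescaled by 0.9 (with a message)
#' until the companion spectral radius drops below 1.
#'
#' @param partition a [module_partition()] (or named list of label vectors).
#' @param intra_gain lag-1 coupling inside a module; must exceed `inter_gain`.
#' @param inter_gain lag-1 coupling between modules, >= 0.
#' @param config a [sim_config()].
#' @param inter_edges_per_pair number of random directed channel pairs
#'   receiving an inter-module edge, for each ordered module pair (default 2).
#' @return list with `recording`, `truth`, the coefficient array
#'   `coefficients` and the stability `radius`.
#' @export
simulate_modular_network <- function(partition, intra_gain = 0.1,
                                     inter_gain = 0.02,
                                     config = sim_config(),
                                     inter_edges_per_pair = 2L) {
  partition <- as_module_partition(partition)
  if (!(intra_gain > inter_gain && inter_gain >= 0)) {
    stop_invalid("need intra_gain > inter_gain >= 0")
  }
  labels <- unlist(partition$modules, use.names = FALSE)
  K <- length(labels)
  module_of <- rep(names(partition$modules), lengths(partition$modules))
  p <- 2L
  A <- array(0, c(K, K, p))
  for (i in seq_len(K)) {
    A[i, i, 1] <- 0.5
    A[i, i, 2] <- -0.15
  }
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i != j && module_of[i] == module_of[j]) A[i, j, 1] <- intra_gain
  }
  if (inter_gain > 0 && inter_edges_per_pair > 0) {
    mods <- names(partition$modules)
    with_seed(sub_seed(config$seed, 999L), {
      for (k in mods) for (l in mods) {
        if (k == l) next
        tgt <- which(module_of == k); srcs <- which(module_of == l)
        pairs <- expand.grid(i = tgt, j = srcs)
        pick <- pairs[sample.int(nrow(pairs),
                                 min(inter_edges_per_pair, nrow(pairs))), ]
        for (r in seq_len(nrow(pick))) {
          A[pick$i[r], pick$j[r], 1] <- inter_gain
        }
      }
    })
  }
  rho <- companion_radius(A)
  tries <- 0L
  while (rho >= 1 && tries < 40L) {
    off <- !diag(K)
    for (m in seq_len(p)) A[, , m][off] <- A[, , m][off] * 0.9
    rho <- companion_radius(A)
    tries <- tries + 1L
    message(sprintf("rescaled couplings by 0.9 (radius now %.3f)", rho))
  }
  if (rho >= 1) stop_invalid("modular system unstable even after rescaling")
  sim <- simulate_mvar_network(A, diag(K), config, labels = labels)
  c(sim[c("recording", "truth")], list(coefficients = A, radius = rho,
                                       partition = partition))
}
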