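#' Normalized Directed Transfer Function (DTF)
#'
#' The squared, row-normalized DTF:
#' `dtf[i, j](f) = |H_ij(f)|^2 / sum_m |H_im(f)|^2`, the causal inflow from
#' channel j to channel i as a fraction of all inflows to i. Values lie in
#' `[0, 1]` and each target row sums to 1 at every frequency. Note this is
#' the squared form; literature using the non-squared `|H|` ratio will report
#' larger off-diagonal values.
#'
#' @param transfer a [transfer_matrix()] object.
#' @return object of class `"conn_spectrum"`: list with `values`
#'   (`K x K x n_freq`, target x source), `frequencies`, `estimator`
#'   (`"DTF"`), `directed = TRUE`, `channel_labels`.
#' @export
dtf <- function(transfer) {
  stopifnot(inherits(transfer, "spectral_transfer"))
  H2 <- abs(transfer$h)^2
  K <- dim(H2)[1]
  vals <- H2
  for (fi in seq_len(dim(H2)[3])) {
    rs <- rowSums(H2[, , fi, drop = FALSE][, , 1])
    if (any(rs == 0)) {
      stop_invalid(sprintf(
        "all-zero transfer row for channel %s at %.3f Hz",
        transfer$channel_labels[which(rs == 0)[1]],
        transfer$frequencies[fi]))
    }
    vals[, , fi] <- H2[, , fi] / rs
  }
  structure(list(values = vals, frequencies = transfer$frequencies,
                 estimator = "DTF", directed = TRUE,
                 channel_labels = transfer$channel_labels),
            class = "conn_spectrum")
}

#' @export
print.conn_spectrum <- function(x, ...) {
  cat(sprintf("<conn_spectrum> %s (%s), %d channels, %d frequencies [%g, %g] Hz\n",
              x$estimator, if (x$directed) "directed" else "undirected",
              dim(x$values)[1], length(x$frequencies),
              min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

# Welch-averaged cross-spectral matrix: Hann taper, segment overlap, returns
# S[i, j, bin] at the native FFT bin frequencies.
welch_cross_spectra <- function(X, sampling_rate, segment_length, overlap) {
  n <- nrow(X); K <- ncol(X)
  seg <- as.integer(segment_length)
  if (seg > n) stop_invalid("segment_length exceeds series length")
  step <- max(1L, as.integer(seg * (1 - overlap)))
  starts <- seq(1L, n - seg + 1L, by = step)
  if (length(starts) < 4) {
    stop_invalid("need at least 4 segments; shorten segment_length")
  }
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg - 1) / (seg - 1))  # Hann
  nf <- seg %/% 2 + 1L
  S <- array(0i, c(K, K, nf))
  for (st in starts) {
    seg_x <- X[st:(st + seg - 1L), , drop = FALSE]
    seg_x <- sweep(seg_x, 2, colMeans(seg_x)) * w
    Fm <- stats::mvfft(seg_x)[seq_len(nf), , drop = FALSE]
    for (i in seq_len(K)) for (j in i:K) {
      cs <- Fm[, i] * Conj(Fm[, j])
      S[i, j, ] <- S[i, j, ] + cs
      if (i != j) S[j, i, ] <- S[j, i, ] + Conj(cs)
    }
  }
  # scale to a density: window power and segment count
  S <- S / (length(starts) * sum(w^2) * sampling_rate)
  list(s = S, frequencies = seq(0, sampling_rate / 2, length.out = nf),
       n_segments = length(starts))
}

#' Magnitude-squared coherence (Welch estimate)
#'
#' Pairwise coherence `|S_ij|^2 / (S_ii S_jj)` from Hann-tapered,
#' overlapping-segment-averaged cross-spectra. Symmetric in (i, j) with a
#' unit diagonal; blind to the direction of coupling and, being bivariate,
#' to common-source confounds.
#'
#' @param rec an [recording()] object.
#' @param segment_length samples per segment (default 256; at 128 Hz this
#'   puts FFT bins on a 0.5 Hz grid).
#' @param overlap fractional segment overlap in `[0, 1)` (default 0.5).
#' @param frequencies optional grid in Hz; each requested frequency is mapped
#'   to the nearest FFT bin. Default: the native bin grid.
#' @return a `"conn_spectrum"` with `estimator = "COH"`,
#'   `directed = FALSE`.
#' @export
coherence <- function(rec, segment_length = 256, overlap = 0.5,
                      frequencies = NULL) {
  stopifnot(inherits(rec, "mc_recording"))
  ws <- welch_cross_spectra(rec$data, rec$sampling_rate, segment_length,
                            overlap)
  K <- n_channels(rec)
  nf <- length(ws$frequencies)
  coh <- array(0, c(K, K, nf))
  for (i in seq_len(K)) for (j in seq_len(K)) {
    coh[i, j, ] <- Mod(ws$s[i, j, ])^2 /
      (Re(ws$s[i, i, ]) * Re(ws$s[j, j, ]))
  }
  coh <- pmin(pmax(coh, 0), 1)
  for (i in seq_len(K)) coh[i, i, ] <- 1
  if (!is.null(frequencies)) {
    idx <- vapply(frequencies, function(f) which.min(abs(ws$frequencies - f)),
                  integer(1))
    coh <- coh[, , idx, drop = FALSE]
  } else {
    frequencies <- ws$frequencies
  }
  structure(list(values = coh, frequencies = frequencies,
                 estimator = "COH", directed = FALSE,
                 channel_labels = rec$channel_labels,
                 n_segments = ws$n_segments),
            class = "conn_spectrum")
}

#' Short-time DTF (SDTF) over an ensemble of trials
#'
#' Time-varying DTF for repeated-trial designs: a short window slides over
#' the epoch; within each window the regression moments are pooled
#' (ensemble-averaged) across all trials, one MVAR is solved per window, and
#' its DTF is computed. Output is ordered by window start time.
#'
#' @param trials list of [recording()] objects of equal length, channel set
#'   and sampling rate; at least 10 trials.
#' @param window_length window size in samples.
#' @param step window hop in samples.
#' @param order MVAR order within each window.
#' @param frequencies grid passed to [transfer_matrix()].
#' @param normalize variance-normalize each trial's channels first.
#' @return object of class `"sdtf_result"`: list with `window_start`
#'   (sample index of each window), `time` (window centre in seconds) and
#'   `spectra` (list of `"conn_spectrum"`).
#' @export
sdtf <- function(trials, window_length, step, order, frequencies = NULL,
                 normalize = TRUE) {
  if (!is.list(trials) || length(trials) < 10) {
    stop_invalid("need an ensemble of at least 10 trials")
  }
  stopifnot(all(vapply(trials, inherits, logical(1), "mc_recording")))
  n <- n_samples(trials[[1]]); K <- n_channels(trials[[1]])
  fs <- trials[[1]]$sampling_rate
  labs <- trials[[1]]$channel_labels
  same <- vapply(trials, function(tr) {
    n_samples(tr) == n && identical(tr$channel_labels, labs) &&
      tr$sampling_rate == fs
  }, logical(1))
  if (!all(same)) stop_invalid("all trials must share length, labels, rate")
  window_length <- as.integer(window_length)
  if (window_length <= order) stop_invalid("window_length must exceed order")
  n_eq <- length(trials) * (window_length - order)
  if (n_eq <= K * order * 2) {
    stop_invalid("under-determined: ", n_eq, " pooled equations for ",
                 K * order, " regressors per channel; use more trials or a",
                 " longer window")
  }
  mats <- lapply(trials, function(tr) {
    X <- sweep(tr$data, 2, colMeans(tr$data))
    if (normalize) X <- sweep(X, 2, apply(X, 2, stats::sd), "/")
    X
  })
  starts <- seq(1L, n - window_length + 1L, by = as.integer(step))
  spectra <- lapply(starts, function(st) {
    ZtZ <- matrix(0, K * order, K * order)
    ZtY <- matrix(0, K * order, K)
    for (X in mats) {
      W <- X[st:(st + window_length - 1L), , drop = FALSE]
      Y <- W[(order + 1):window_length, , drop = FALSE]
      Z <- do.call(cbind, lapply(seq_len(order), function(m) {
        W[(order + 1 - m):(window_length - m), , drop = FALSE]
      }))
      ZtZ <- ZtZ + crossprod(Z)
      ZtY <- ZtY + crossprod(Z, Y)
    }
    B <- solve(ZtZ, ZtY)
    A <- array(0, c(K, K, order))
    for (m in seq_len(order)) {
      A[, , m] <- t(B[((m - 1) * K + 1):(m * K), , drop = FALSE])
    }
    model <- list(coefficients = A, sampling_rate = fs,
                  channel_labels = labs)
    dtf(transfer_matrix(model, frequencies))
  })
  structure(list(window_start = starts,
                 time = (starts - 1 + window_length / 2) / fs,
                 spectra = spectra, window_length = window_length,
                 order = order, n_trials = length(trials)),
            class = "sdtf_result")
}

#' Integrate a connectivity spectrum over a frequency band
#'
#' Arithmetic mean of the per-frequency values over all grid points in the
#' closed interval `[f_lo, f_hi]`. Conventional bands: 0.5–40, 1–45 and
#' 4–60 Hz.
#'
#' @param spectrum a `"conn_spectrum"` (from [dtf()] or [coherence()]).
#' @param f_lo,f_hi band edges in Hz, inclusive on both sides.
#' @return object of class `"integrated_conn"`: list with `values`
#'   (`K x K`, target x source), `band`, `estimator`, `directed`,
#'   `channel_labels`.
#' @export
band_integrate <- function(spectrum, f_lo, f_hi) {
  stopifnot(inherits(spectrum, "conn_spectrum"))
  if (!(f_lo < f_hi)) stop_invalid("need f_lo < f_hi")
  sel <- spectrum$frequencies >= f_lo & spectrum$frequencies <= f_hi
  if (!any(sel)) stop_invalid("band [", f_lo, ", ", f_hi,
                              "] contains no grid point")
  vals <- apply(spectrum$values[, , sel, drop = FALSE], c(1, 2), mean)
  dimnames(vals) <- list(spectrum$channel_labels, spectrum$channel_labels)
  structure(list(values = vals, band = c(f_lo, f_hi),
                 estimator = spectrum$estimator, directed = spectrum$directed,
                 channel_labels = spectrum$channel_labels),
            class = "integrated_conn")
}

#' @export
print.integrated_conn <- function(x, ...) {
  cat(sprintf("<integrated_conn> %s over [%g, %g] Hz (%s)\n", x$estimator,
              x$band[1], x$band[2],
              if (x$directed) "target x source" else "symmetric"))
  print(round(x$values, 3))
  invisible(x)
}
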