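#' Phase-randomized surrogate of a signal
#'
#' Fourier-amplitude-preserving surrogate: the magnitude spectrum is kept and
#' the phases are replaced by i.i.d. uniform draws (with Hermitian symmetry,
#' so the output is real). Applied channel-wise with independent phases, this
#' destroys every cross-channel dependence while preserving each channel's
#' power spectrum — the null model for edge existence.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @export
phase_surrogate <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  half <- (n - 1L) %/% 2L
  if (half >= 1) {
    ph <- stats::runif(half, 0, 2 * pi)
    X[2:(half + 1)] <- Mod(X[2:(half + 1)]) * exp(1i * ph)
    X[n:(n - half + 1)] <- Conj(X[2:(half + 1)])
  }
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Surrogate-null significance thresholds for band-integrated DTF
#'
#' Builds the null distribution of each directed pair's band-integrated DTF
#' by repeatedly (a) phase-randomizing every channel independently (which
#' removes all cross-channel coupling but keeps the spectra), (b) refitting
#' the MVAR and (c) recomputing band-integrated DTF. The per-pair threshold
#' is the `level` quantile of that null. Note this is a null for edge
#' *existence*; resampling the original data without destroying dependence
#' would preserve the very coupling under test. For confidence intervals
#' around the observed DTF use [dtf_bootstrap_ci()].
#'
#' @param rec an [recording()] object.
#' @param order MVAR order used for each refit.
#' @param band frequency band `c(f_lo, f_hi)` in Hz (default `c(1, 45)`).
#' @param n_resamples number of surrogate draws (>= 100 recommended at
#'   level 0.9; a warning is issued below that).
#' @param level null quantile defining significance (default 0.9, i.e. the
#'   90th percentile).
#' @param frequencies grid passed to [transfer_matrix()].
#' @param seed integer seed; the procedure is deterministic given it.
#' @param normalize passed to [fit_mvar()].
#' @return object of class `"signif_thresholds"`: list with `thresholds`
#'   (`K x K`, target x source, `NA` diagonal), `level`, `n_resamples`,
#'   `band`, `channel_labels`.
#' @export
resampling_thresholds <- function(rec, order, band = c(1, 45),
                                  n_resamples = 200, level = 0.9,
                                  frequencies = NULL, seed = NULL,
                                  normalize = TRUE) {
  stopifnot(inherits(rec, "mc_recording"))
  n_resamples <- as.integer(n_resamples)
  if (n_resamples < 1) stop_invalid("n_resamples must be >= 1")
  if (n_resamples < 100) {
    warning("fewer than 100 resamples makes the ", level,
            " quantile unreliable", call. = FALSE)
  }
  K <- n_channels(rec)
  draws <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(r) {
      surr <- rec
      surr$data <- apply(rec$data, 2, phase_surrogate)
      fit <- suppressWarnings(fit_mvar(surr, order, normalize = normalize))
      band_integrate(dtf(transfer_matrix(fit, frequencies)),
                     band[1], band[2])$values
    }, matrix(0, K, K))
  })
  thr <- apply(draws, c(1, 2), stats::quantile, probs = level, names = FALSE)
  diag(thr) <- NA_real_
  dimnames(thr) <- list(rec$channel_labels, rec$channel_labels)
  structure(list(thresholds = thr, level = level, n_resamples = n_resamples,
                 band = band, channel_labels = rec$channel_labels),
            class = "signif_thresholds")
}

#' @export
print.signif_thresholds <- function(x, ...) {
  cat(sprintf(
    "<signif_thresholds> level %.2f from %d surrogates, band [%g, %g] Hz\n",
    x$level, x$n_resamples, x$band[1], x$band[2]))
  print(round(x$thresholds, 4))
  invisible(x)
}

#' Epoch-resampling bootstrap confidence intervals for band-integrated DTF
#'
#' Resamples contiguous epochs of the recording with replacement, refits the
#' MVAR and recomputes band-integrated DTF, giving percentile confidence
#' intervals around the *observed* values (it preserves coupling, so it is
#' not a significance null — see [resampling_thresholds()] for that).
#'
#' @inheritParams resampling_thresholds
#' @param epoch_length epoch size in samples.
#' @param n_boot number of bootstrap resamples.
#' @param probs quantiles to report (default `c(0.05, 0.95)`).
#' @return list with `quantiles` (array `K x K x length(probs)`) and the
#'   observed `values`.
#' @export
dtf_bootstrap_ci <- function(rec, order, band = c(1, 45),
                             epoch_length = 256, n_boot = 200,
                             probs = c(0.05, 0.95), frequencies = NULL,
                             seed = NULL, normalize = TRUE) {
  stopifnot(inherits(rec, "mc_recording"))
  n <- n_samples(rec); K <- n_channels(rec)
  n_ep <- n %/% epoch_length
  if (n_ep < 4) stop_invalid("need at least 4 epochs")
  obs <- band_integrate(
    dtf(transfer_matrix(suppressWarnings(
      fit_mvar(rec, order, normalize = normalize)), frequencies)),
    band[1], band[2])$values
  draws <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      pick <- sample.int(n_ep, n_ep, replace = TRUE)
      rows <- unlist(lapply(pick, function(e) {
        ((e - 1L) * epoch_length + 1L):(e * epoch_length)
      }))
      boot <- rec
      boot$data <- rec$data[rows, , drop = FALSE]
      fit <- suppressWarnings(fit_mvar(boot, order, normalize = normalize))
      band_integrate(dtf(transfer_matrix(fit, frequencies)),
                     band[1], band[2])$values
    }, matrix(0, K, K))
  })
  qs <- apply(draws, c(1, 2), stats::quantile, probs = probs, names = FALSE)
  qs <- aperm(qs, c(2, 3, 1))
  dimnames(qs) <- list(rec$channel_labels, rec$channel_labels,
                       paste0("q", probs))
  list(quantiles = qs, values = obs)
}

#' Binarize an integrated connectivity matrix into an adjacency
#'
#' An edge is present iff its value is *strictly greater* than its threshold
#' (ties are excluded); the diagonal is always absent. The threshold is
#' either a single number applied to all pairs (the fixed-cutoff path, e.g.
#' 0.05, also used for SL) or a complete [resampling_thresholds()] table.
#'
#' @param integrated an `"integrated_conn"` (or `"pair_matrix"`, which is
#'   adapted via [as_integrated()]).
#' @param threshold scalar in `[0, 1]` or a `"signif_thresholds"` object
#'   whose labels match.
#' @return object of class `"adjacency"`: list with logical `matrix`
#'   (target x source), `directed`, `threshold` description.
#' @export
binarize <- function(integrated, threshold) {
  if (inherits(integrated, "pair_matrix")) {
    integrated <- as_integrated(integrated)
  }
  stopifnot(inherits(integrated, "integrated_conn"))
  vals <- integrated$values
  K <- nrow(vals)
  if (inherits(threshold, "signif_thresholds")) {
    if (!identical(threshold$channel_labels, integrated$channel_labels)) {
      stop_invalid("threshold table labels do not match the matrix")
    }
    thr <- threshold$thresholds
    if (any(is.na(thr[!diag(K)]))) {
      stop_invalid("incomplete threshold table")
    }
    desc <- sprintf("surrogate level %.2f", threshold$level)
  } else {
    if (!is.numeric(threshold) || length(threshold) != 1 ||
        threshold < 0 || threshold > 1) {
      stop_invalid("scalar threshold must lie in [0, 1]")
    }
    thr <- matrix(threshold, K, K)
    desc <- sprintf("fixed %.4g", threshold)
  }
  adj <- !is.na(vals) & vals > thr
  diag(adj) <- FALSE
  dimnames(adj) <- list(integrated$channel_labels,
                        integrated$channel_labels)
  structure(list(matrix = adj, directed = integrated$directed,
                 threshold = desc, estimator = integrated$estimator,
                 channel_labels = integrated$channel_labels),
            class = "adjacency")
}

#' @export
print.adjacency <- function(x, ...) {
  ne <- if (x$directed) sum(x$matrix) else sum(x$matrix) / 2
  cat(sprintf("<adjacency> %s, %s, %d edges (threshold %s)\n", x$estimator,
              if (x$directed) "directed" else "undirected", ne, x$threshold))
  invisible(x)
}
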