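#' Fit a multivariate autoregressive (MVAR) model
#'
#' Joint multichannel least squares: all channels are regressed
#' simultaneously on the past `order` samples of *every* channel, minimizing
#' the one-step-ahead squared prediction error. Channels are zero-meaned and,
#' by default, variance-normalized before fitting so that transfer-derived
#' quantities are comparable across channels.
#'
#' The fitted model is `x_t = sum_{m=1..p} A_m x_{t-m} + e_t` with residual
#' covariance `V`. Stability (companion spectral radius < 1) is checked after
#' fitting; an unstable fit is returned with `stable = FALSE` and a warning,
#' not an error, since borderline fits occur on real noisy data.
#'
#' @param rec an [recording()] object.
#' @param order model order p >= 1.
#' @param normalize scale channels to unit variance before fitting
#'   (default `TRUE`).
#' @return object of class `"mvar_model"`: list with `coefficients`
#'   (`K x K x p` array, `coefficients[i, j, m]` = influence of channel j at
#'   lag m on channel i), `residual_cov`, `order`, `sampling_rate`,
#'   `channel_labels`, `stable`, `radius`, `n_obs`, `logdet_v`.
#' @examples
#' sim <- simulate_common_source(2, c(2, 4), sim_config(seed = 1))
#' fit_mvar(sim$recording, order = 6)
#' @export
fit_mvar <- function(rec, order, normalize = TRUE) {
  stopifnot(inherits(rec, "mc_recording"))
  order <- as.integer(order)
  if (order < 1) stop_invalid("order must be >= 1")
  X <- rec$data
  n <- nrow(X); K <- ncol(X)
  if (n - order <= K * order) {
    stop_invalid("too few samples (", n, ") for order ", order,
                 " with ", K, " channels")
  }
  if (n <= order * K * 10) {
    warning("sample size ", n, " is small for order ", order, " with ", K,
            " channels; coefficient estimates will be noisy", call. = FALSE)
  }
  X <- sweep(X, 2, colMeans(X))
  if (normalize) X <- sweep(X, 2, apply(X, 2, stats::sd), "/")
  Y <- X[(order + 1):n, , drop = FALSE]
  Z <- do.call(cbind, lapply(seq_len(order), function(m) {
    X[(order + 1 - m):(n - m), , drop = FALSE]
  }))
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) {
    bad_cols <- qrz$pivot[(qrz$rank + 1):ncol(Z)]
    bad_ch <- sort(unique((bad_cols - 1L) %% K + 1L))
    stop_invalid("rank-deficient regressor matrix; offending channel(s): ",
                 paste(rec$channel_labels[bad_ch], collapse = ", "),
                 " (duplicated or linearly dependent channels?)")
  }
  B <- qr.coef(qrz, Y)                       # (K * p) x K
  E <- Y - Z %*% B
  V <- crossprod(E) / (nrow(Y) - ncol(Z))
  A <- array(0, c(K, K, order))
  for (m in seq_len(order)) {
    A[, , m] <- t(B[((m - 1) * K + 1):(m * K), , drop = FALSE])
  }
  rho <- companion_radius(A)
  stable <- rho < 1
  if (!stable) {
    warning(sprintf("fitted MVAR model is unstable (radius %.3f)", rho),
            call. = FALSE)
  }
  structure(list(coefficients = A, residual_cov = V, order = order,
                 sampling_rate = rec$sampling_rate,
                 channel_labels = rec$channel_labels,
                 stable = stable, radius = rho, n_obs = nrow(Y),
                 logdet_v = determinant(V, logarithm = TRUE)$modulus[1]),
            class = "mvar_model")
}

#' @export
print.mvar_model <- function(x, ...) {
  K <- length(x$channel_labels)
  cat(sprintf("<mvar_model> order %d, %d channels @ %g Hz, %s (radius %.3f)\n",
              x$order, K, x$sampling_rate,
              if (x$stable) "stable" else "UNSTABLE", x$radius))
  invisible(x)
}

#' Select the MVAR model order by information criterion
#'
#' Fits orders `1..max_order` on a common sample (the first `max_order`
#' rows are dropped for every candidate so likelihoods are comparable) and
#' returns the order minimizing the criterion.
#'
#' @param rec an [recording()] object.
#' @param max_order largest candidate order.
#' @param criterion `"aic"` (default) or `"bic"`.
#' @param normalize passed to [fit_mvar()].
#' @return the selected order (integer), with the criterion table in
#'   attribute `"criterion_table"`.
#' @export
select_order <- function(rec, max_order, criterion = c("aic", "bic"),
                         normalize = TRUE) {
  stopifnot(inherits(rec, "mc_recording"))
  criterion <- match.arg(criterion)
  max_order <- as.integer(max_order)
  if (max_order < 1) stop_invalid("max_order must be >= 1")
  n <- n_samples(rec); K <- n_channels(rec)
  if (n - max_order <= K * max_order + 1) {
    stop_invalid("max_order ", max_order, " too large for ", n, " samples")
  }
  neff <- n - max_order
  vals <- vapply(seq_len(max_order), function(p) {
    # drop leading rows so every candidate predicts the same targets
    sub <- rec
    sub$data <- rec$data[(max_order - p + 1):n, , drop = FALSE]
    fit <- suppressWarnings(fit_mvar(sub, p, normalize = normalize))
    pen <- if (criterion == "aic") 2 else log(neff)
    neff * fit$logdet_v + pen * K * K * p
  }, numeric(1))
  best <- which.min(vals)
  structure(as.integer(best),
            criterion_table = data.frame(order = seq_len(max_order),
                                         value = vals))
}

#' Spectral transfer matrix H(f) of an MVAR model
#'
#' At each frequency the characteristic matrix
#' `A(f) = I - sum_m A_m exp(-2i pi f m / fs)` is inverted:
#' `H(f) = A(f)^{-1}`. `H[i, j](f)` carries the transfer from source channel
#' j to target channel i.
#'
#' @param model an [fit_mvar()] model (or any list with `coefficients`,
#'   `sampling_rate`, `channel_labels`).
#' @param frequencies strictly increasing grid in Hz within `[0, Nyquist]`;
#'   default 0 to Nyquist in 0.5 Hz steps, which resolves the conventional
#'   analysis bands (0.5–40, 1–45, 4–60 Hz) exactly.
#' @return object of class `"spectral_transfer"`: list with complex array
#'   `h` (`K x K x n_freq`), `frequencies`, `sampling_rate`,
#'   `channel_labels`.
#' @export
transfer_matrix <- function(model, frequencies = NULL) {
  A <- model$coefficients
  fs <- model$sampling_rate
  K <- dim(A)[1]; p <- dim(A)[3]
  if (is.null(frequencies)) frequencies <- seq(0, fs / 2, by = 0.5)
  if (is.unsorted(frequencies, strictly = TRUE)) {
    stop_invalid("frequency grid must be strictly increasing")
  }
  if (min(frequencies) < 0 || max(frequencies) > fs / 2 + 1e-9) {
    stop_invalid("frequencies must lie in [0, Nyquist]")
  }
  H <- array(0i, c(K, K, length(frequencies)))
  I <- diag(K)
  for (fi in seq_along(frequencies)) {
    f <- frequencies[fi]
    Af <- I + 0i
    for (m in seq_len(p)) Af <- Af - A[, , m] * exp(-2i * pi * f * m / fs)
    Hf <- tryCatch(solve(Af), error = function(e) {
      stop_invalid(sprintf(
        "characteristic matrix singular at %.3f Hz (%s)", f,
        conditionMessage(e)))
    })
    H[, , fi] <- Hf
  }
  structure(list(h = H, frequencies = frequencies, sampling_rate = fs,
                 channel_labels = model$channel_labels),
            class = "spectral_transfer")
}

#' Model-implied spectral density matrix
#'
#' `S(f) = H(f) V H(f)^H / fs`, the two-sided cross-spectral density of the
#' fitted MVAR process (units: variance per Hz). The diagonal is real and
#' non-negative and `S(f)` is Hermitian at every frequency.
#'
#' @inheritParams transfer_matrix
#' @return object of class `"spectral_density"`: complex array `s`
#'   (`K x K x n_freq`) plus grid metadata.
#' @export
spectral_density <- function(model, frequencies = NULL) {
  tr <- transfer_matrix(model, frequencies)
  V <- model$residual_cov
  K <- dim(tr$h)[1]
  S <- array(0i, dim(tr$h))
  for (fi in seq_along(tr$frequencies)) {
    Hf <- tr$h[, , fi]
    Sf <- Hf %*% V %*% Conj(t(Hf)) / model$sampling_rate
    Sf <- (Sf + Conj(t(Sf))) / 2          # enforce exact Hermitian symmetry
    S[, , fi] <- Sf
  }
  structure(list(s = S, frequencies = tr$frequencies,
                 sampling_rate = model$sampling_rate,
                 channel_labels = model$channel_labels),
            class = "spectral_density")
}
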