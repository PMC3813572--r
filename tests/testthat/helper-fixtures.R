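# Shared fixtures: small stable MVAR systems with known coefficients, white
# recordings, and a bare model constructor for transfer-level tests.

# stable 5-channel order-3 system used for parameter-recovery checks
fixture_ar3_5ch <- function() {
  A <- array(0, c(5, 5, 3))
  for (i in 1:5) A[i, i, 1] <- 0.4
  A[2, 1, 1] <- 0.3
  A[3, 2, 1] <- -0.25
  A[4, 5, 1] <- 0.2
  for (i in 1:5) A[i, i, 2] <- -0.2
  A[5, 1, 2] <- 0.15
  A[1, 3, 2] <- -0.2
  for (i in 1:5) A[i, i, 3] <- 0.1
  A[4, 2, 3] <- 0.15
  A
}

# 3-channel order-2 chain 1 -> 2 -> 3 with unequal innovation variances
fixture_ar2_3ch <- function() {
  A <- array(0, c(3, 3, 2))
  for (i in 1:3) A[i, i, 1] <- 0.5
  A[2, 1, 1] <- 0.4
  A[3, 2, 1] <- 0.3
  for (i in 1:3) A[i, i, 2] <- -0.3
  list(A = A, V = diag(c(1, 0.8, 1.2)))
}

white_recording <- function(n, K, seed, fs = 128) {
  set.seed(seed)
  recording(matrix(rnorm(n * K), n, K), fs, paste0("ch", seq_len(K)))
}

# minimal model object accepted by transfer_matrix()/spectral_density()
bare_model <- function(A, V = NULL, fs = 128, labels = NULL) {
  A <- if (length(dim(A)) == 2) array(A, c(dim(A), 1)) else A
  K <- dim(A)[1]
  if (is.null(labels)) labels <- paste0("ch", seq_len(K))
  list(coefficients = A, residual_cov = if (is.null(V)) diag(K) else V,
       sampling_rate = fs, channel_labels = labels)
}

# adjacency object from a plain logical matrix (target x source)
adjacency_from_matrix <- function(m, labels, directed = TRUE) {
  dimnames(m) <- list(labels, labels)
  structure(list(matrix = m, directed = directed, threshold = "fixture",
                 estimator = "FIX", channel_labels = labels),
            class = "adjacency")
}
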