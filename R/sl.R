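#' Synchronization likelihood parameters
#'
#' Time-delay embedding and recurrence settings for
#' [synchronization_likelihood()]. The reference probability `p_ref` sets the
#' per-channel recurrence rate: for each embedded vector, the critical
#' distance is its k-th nearest-neighbour distance with
#' `k = round(p_ref * n_valid)`, so the target rate is attained exactly. The
#' Theiler window excludes temporally adjacent (autocorrelated) vectors from
#' the neighbour search; the default `delay * embedding_dim` spans the whole
#' embedding window.
#'
#' @param delay embedding delay in samples (default 10).
#' @param embedding_dim embedding dimension (default 10).
#' @param p_ref recurrence probability in (0, 1) (default 0.05).
#' @param theiler_window minimum temporal separation, in samples, between a
#'   vector and its candidate neighbours.
#' @return list of class `"sl_params"`.
#' @export
sl_params <- function(delay = 10L, embedding_dim = 10L, p_ref = 0.05,
                      theiler_window = delay * embedding_dim) {
  if (delay < 1 || embedding_dim < 2) {
    stop_invalid("need delay >= 1 and embedding_dim >= 2")
  }
  if (!(p_ref > 0 && p_ref < 1)) stop_invalid("p_ref must be in (0, 1)")
  structure(list(delay = as.integer(delay),
                 embedding_dim = as.integer(embedding_dim),
                 p_ref = p_ref, theiler_window = as.integer(theiler_window)),
            class = "sl_params")
}

# k-nearest-neighbour sets per embedded vector (Theiler-corrected).
# Returns list(neighbors = list of integer vectors, k = integer vector).
sl_neighbor_sets <- function(x, params) {
  m <- params$embedding_dim; d <- params$delay
  N <- length(x) - (m - 1L) * d
  emb <- vapply(seq_len(m), function(j) x[(1:N) + (j - 1L) * d],
                numeric(N))
  dm <- as.matrix(stats::dist(emb))
  idx <- seq_len(N)
  neighbors <- vector("list", N)
  k_of <- integer(N)
  for (i in idx) {
    valid <- idx[abs(idx - i) > params$theiler_window]
    M <- length(valid)
    if (M < 2) stop_invalid("Theiler window leaves no valid neighbours")
    k <- max(1L, as.integer(round(params$p_ref * M)))
    dv <- dm[i, valid]
    ord <- order(dv)[seq_len(k)]
    neighbors[[i]] <- valid[ord]
    k_of[i] <- k
  }
  list(neighbors = neighbors, k = k_of)
}

#' Synchronization likelihood (SL)
#'
#' Bivariate recurrence-coincidence measure on time-delay-embedded signals:
#' for each reference time i, each channel's critical distance is set so that
#' a fraction `p_ref` of (Theiler-valid) embedded vectors count as
#' recurrences; the SL of a channel pair is the number of *coincident*
#' recurrences divided by its expectation under the per-channel rate,
#' `SL = sum_i |N_x(i) & N_y(i)| / sum_i k_i`. Identical channels give
#' SL = 1; independent channels give SL near the chance level `p_ref`.
#'
#' @param rec an [recording()] object.
#' @param params an [sl_params()] object.
#' @return object of class `"pair_matrix"`: list with the symmetric `values`
#'   matrix (unit diagonal), `estimator = "SL"`, `params`,
#'   `channel_labels`.
#' @export
synchronization_likelihood <- function(rec, params = sl_params()) {
  stopifnot(inherits(rec, "mc_recording"), inherits(params, "sl_params"))
  n <- n_samples(rec); K <- n_channels(rec)
  span <- (params$embedding_dim - 1L) * params$delay
  if (span >= n) {
    stop_invalid("embedding window ((dim-1)*delay = ", span,
                 ") must be shorter than the series (", n, " samples)")
  }
  sets <- lapply(seq_len(K), function(ch) {
    sl_neighbor_sets(rec$data[, ch], params)
  })
  vals <- diag(K)
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    hits <- sum(vapply(seq_along(sets[[i]]$neighbors), function(t) {
      length(intersect(sets[[i]]$neighbors[[t]], sets[[j]]$neighbors[[t]]))
    }, numeric(1)))
    sl <- hits / sum(sets[[i]]$k)
    vals[i, j] <- sl
    vals[j, i] <- sl
  }
  dimnames(vals) <- list(rec$channel_labels, rec$channel_labels)
  structure(list(values = vals, estimator = "SL", params = params,
                 directed = FALSE, channel_labels = rec$channel_labels),
            class = "pair_matrix")
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("<pair_matrix> %s, %d channels\n", x$estimator,
              nrow(x$values)))
  print(round(x$values, 3))
  invisible(x)
}

#' Treat a pair matrix as a band-integrated connectivity matrix
#'
#' SL has no frequency axis; this adapter wraps a `"pair_matrix"` in the
#' `"integrated_conn"` shape so the thresholding and network stages accept
#' it alongside band-integrated DTF or coherence.
#'
#' @param pm a `"pair_matrix"` (from [synchronization_likelihood()]).
#' @return an `"integrated_conn"` with `band = NA`.
#' @export
as_integrated <- function(pm) {
  stopifnot(inherits(pm, "pair_matrix"))
  structure(list(values = pm$values, band = c(NA_real_, NA_real_),
                 estimator = pm$estimator, directed = FALSE,
                 channel_labels = pm$channel_labels),
            class = "integrated_conn")
}
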