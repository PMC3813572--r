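#' Node degrees of an adjacency
#'
#' For a directed adjacency (target x source) the out-degree of a channel is
#' the number of edges it sends and the in-degree the number it receives;
#' for an undirected adjacency each edge counts once per endpoint.
#'
#' @param adj an [binarize()] adjacency.
#' @return data frame with one row per channel: `channel` plus either
#'   `out_degree` and `in_degree` (directed) or `degree` (undirected).
#' @export
node_degrees <- function(adj) {
  stopifnot(inherits(adj, "adjacency"))
  A <- adj$matrix
  if (adj$directed) {
    data.frame(channel = adj$channel_labels,
               out_degree = as.integer(colSums(A)),
               in_degree = as.integer(rowSums(A)),
               row.names = NULL)
  } else {
    data.frame(channel = adj$channel_labels,
               degree = as.integer(rowSums(A)),
               row.names = NULL)
  }
}

edge_list <- function(adj) {
  idx <- which(adj$matrix, arr.ind = TRUE)
  df <- data.frame(source = adj$channel_labels[idx[, 2]],
                   target = adj$channel_labels[idx[, 1]])
  if (!adj$directed) {
    keep <- match(df$source, adj$channel_labels) <
      match(df$target, adj$channel_labels)
    df <- df[keep, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

pair_key <- function(source, target, directed) {
  if (directed) paste(source, target, sep = "->")
  else paste(pmin(source, target), pmax(source, target), sep = "--")
}

#' Score an estimated adjacency against the ground truth
#'
#' Each estimated edge is matched against the known network:
#' direction-sensitively when `respect_direction = TRUE` and the adjacency is
#' directed, otherwise against the undirected skeleton of the truth (the
#' natural comparison for symmetric estimators such as coherence or SL).
#' Always, `true_detected + missed = |truth|`.
#'
#' @param adj an [binarize()] adjacency.
#' @param truth a [ground_truth()] network over the same channel labels.
#' @param respect_direction compare edge directions (forced `FALSE` for
#'   undirected adjacencies).
#' @return object of class `"edge_classification"`: list of counts
#'   (`n_true_detected`, `n_false_positive`, `n_missed`, `n_truth`) and an
#'   `edges` data frame with a `status` column.
#' @export
classify_edges <- function(adj, truth, respect_direction = TRUE) {
  stopifnot(inherits(adj, "adjacency"), inherits(truth, "ground_truth"))
  if (!setequal(adj$channel_labels, truth$labels)) {
    stop_invalid("adjacency and truth have different channel label sets")
  }
  directed <- respect_direction && adj$directed
  est <- edge_list(adj)
  est_keys <- unique(pair_key(est$source, est$target, directed))
  truth_keys <- unique(pair_key(truth$edges$source, truth$edges$target,
                                directed))
  tp <- intersect(est_keys, truth_keys)
  fp <- setdiff(est_keys, truth_keys)
  miss <- setdiff(truth_keys, est_keys)
  edges <- rbind(
    if (length(tp)) data.frame(edge = tp, status = "true_detected"),
    if (length(fp)) data.frame(edge = fp, status = "false_positive"),
    if (length(miss)) data.frame(edge = miss, status = "missed"))
  structure(list(n_true_detected = length(tp),
                 n_false_positive = length(fp),
                 n_missed = length(miss),
                 n_truth = length(truth_keys),
                 directed = directed,
                 edges = if (is.null(edges)) {
                   data.frame(edge = character(), status = character())
                 } else edges),
            class = "edge_classification")
}

#' @export
print.edge_classification <- function(x, ...) {
  cat(sprintf(
    "<edge_classification> %s: %d true detected, %d false positive, %d missed (|truth| = %d)\n",
    if (x$directed) "directed" else "undirected", x$n_true_detected,
    x$n_false_positive, x$n_missed, x$n_truth))
  invisible(x)
}

#' Module partition of the channel set
#'
#' A named, ordered assignment of channel labels to modules; modules must be
#' disjoint and there must be at least two of them.
#'
#' @param modules named list, one character vector of labels per module.
#' @return object of class `"module_partition"`.
#' @export
module_partition <- function(modules) {
  if (is.null(names(modules)) || any(names(modules) == "")) {
    stop_invalid("every module needs a name")
  }
  labs <- unlist(modules, use.names = FALSE)
  if (anyDuplicated(labs)) {
    stop_invalid("modules overlap: ",
                 paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  if (length(modules) < 2) stop_invalid("need at least 2 modules")
  structure(list(modules = lapply(modules, as.character),
                 module_order = names(modules)),
            class = "module_partition")
}

as_module_partition <- function(x) {
  if (inherits(x, "module_partition")) x else module_partition(x)
}

#' Default frontal/central/parietal module partition
#'
#' The four scalp modules conventionally used for 10-20 recordings: frontal
#' F (Fp1, Fp2, Fpz, F3, F4, Fz, F7, F8), central C (C3, Cz, C4, Cp5, Cp6)
#' and two parietal modules PL (P7, P3, O1) and PR (P8, P4, O2). The midline
#' electrode Pz sits between the two parietal modules; it is assigned to one
#' of them via `pz` (default `"PL"`).
#'
#' @param pz `"PL"` or `"PR"`: which parietal module receives Pz.
#' @return a [module_partition()].
#' @export
default_partition_1020 <- function(pz = c("PL", "PR")) {
  pz <- match.arg(pz)
  mods <- list(F  = c("Fp1", "Fp2", "Fpz", "F3", "F4", "Fz", "F7", "F8"),
               C  = c("C3", "Cz", "C4", "Cp5", "Cp6"),
               PL = c("P7", "P3", "O1"),
               PR = c("P8", "P4", "O2"))
  mods[[pz]] <- c(mods[[pz]], "Pz")
  module_partition(mods)
}

#' Assortative-mixing coupling matrix E
#'
#' Module-by-module coupling: `E[k, l]` aggregates the band-integrated
#' connectivity over all ordered channel pairs with the source in module l
#' and the target in module k (self-pairs excluded), keeping only values
#' strictly above `threshold`. The default aggregation is the sum of the
#' qualifying values (a fraction-of-coupling reading once normalized);
#' `aggregate = "mean"` divides each block by its pair count instead. The
#' matrix is then normalized so all elements sum to 1. Rows are target
#' modules, columns source modules. Diagonal dominance of E (each `E[k, k]`
#' above the mean of its off-diagonal row and column entries) indicates
#' assortative, modular coupling.
#'
#' @param integrated an `"integrated_conn"` (or `"pair_matrix"`).
#' @param partition a [module_partition()] covering all channels.
#' @param threshold fixed cutoff in `[0, 1]`; only values strictly above it
#'   contribute (default 0.05).
#' @param aggregate `"sum"` (default) or `"mean"`.
#' @param normalize divide by the grand total (default `TRUE`).
#' @return object of class `"mixing_matrix"`: list with `e` (module x
#'   module), `normalized`, `estimator`, `threshold`, `partition`.
#' @export
mixing_matrix <- function(integrated, partition, threshold = 0.05,
                          aggregate = c("sum", "mean"), normalize = TRUE) {
  if (inherits(integrated, "pair_matrix")) {
    integrated <- as_integrated(integrated)
  }
  stopifnot(inherits(integrated, "integrated_conn"))
  aggregate <- match.arg(aggregate)
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop_invalid("threshold must lie in [0, 1]")
  }
  partition <- as_module_partition(partition)
  labs <- integrated$channel_labels
  part_labs <- unlist(partition$modules, use.names = FALSE)
  if (!setequal(part_labs, labs)) {
    stop_invalid("partition must cover exactly the matrix channels")
  }
  if (any(lengths(partition$modules) < 2)) {
    warning("module(s) with a single channel: their diagonal block has no ",
            "channel pair and is set to 0", call. = FALSE)
  }
  mods <- partition$module_order
  nm <- length(mods)
  E <- matrix(0, nm, nm, dimnames = list(mods, mods))
  vals <- integrated$values
  for (k in seq_len(nm)) for (l in seq_len(nm)) {
    tgt <- match(partition$modules[[mods[k]]], labs)
    src <- match(partition$modules[[mods[l]]], labs)
    block <- vals[tgt, src, drop = FALSE]
    if (k == l) {
      keep <- !diag(length(tgt))
      block <- block[keep]
    }
    n_pairs <- length(block)
    if (n_pairs == 0) { E[k, l] <- 0; next }
    passing <- block[block > threshold]
    E[k, l] <- if (aggregate == "sum") sum(passing)
               else sum(passing) / n_pairs
  }
  normalized <- FALSE
  tot <- sum(E)
  if (normalize) {
    if (tot > 0) {
      E <- E / tot
      normalized <- TRUE
    } else {
      warning("no connection exceeds the threshold; returning unnormalized",
              " zero matrix", call. = FALSE)
    }
  }
  structure(list(e = E, normalized = normalized,
                 estimator = integrated$estimator, threshold = threshold,
                 aggregate = aggregate, band = integrated$band,
                 partition = partition),
            class = "mixing_matrix")
}

#' @export
print.mixing_matrix <- function(x, ...) {
  cat(sprintf("<mixing_matrix> %s, %s%s (rows = target module, cols = source)\n",
              x$estimator, x$aggregate,
              if (x$normalized) ", normalized to sum 1" else ""))
  print(round(x$e, 4))
  invisible(x)
}

#' Assortativity report for a mixing matrix
#'
#' For each module k, compares the intra-module coupling `E[k, k]` with the
#' mean of its off-diagonal row and column entries (coupling to and from
#' other modules). The global flag is `TRUE` iff every diagonal element
#' exceeds its off-diagonal mean — the signature of strongly bound modules
#' exchanging information through weaker links. Ratios against a zero
#' off-diagonal mean are reported as the capped sentinel `1e6`.
#'
#' @param mm a normalized [mixing_matrix()].
#' @return data frame (per module: `e_kk`, `off_diag_mean`, `ratio`) with
#'   attribute `"assortative"` (logical flag).
#' @export
assortativity_report <- function(mm) {
  stopifnot(inherits(mm, "mixing_matrix"))
  if (!mm$normalized) stop_invalid("mixing matrix must be normalized")
  E <- mm$e
  nm <- nrow(E)
  rows <- lapply(seq_len(nm), function(k) {
    off <- c(E[k, -k], E[-k, k])
    om <- mean(off)
    ratio <- if (om > 0) E[k, k] / om else if (E[k, k] > 0) 1e6 else NA_real_
    data.frame(module = rownames(E)[k], e_kk = E[k, k], off_diag_mean = om,
               ratio = min(ratio, 1e6))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "assortative") <- all(out$e_kk > out$off_diag_mean)
  out
}
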