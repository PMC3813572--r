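#' Multichannel recording container
#'
#' The basic data structure consumed by every estimator: a numeric matrix of
#' amplitudes with time samples in rows and channels in columns, a sampling
#' rate in Hz and one unique label per channel (conventionally 10-20 montage
#' names such as `"Fp1"` or `"Pz"`).
#'
#' @param data numeric matrix, time samples in rows, channels in columns.
#'   Must be free of missing values, have at least two channels and more than
#'   ten times as many samples as channels.
#' @param sampling_rate sampling rate in Hz, a single positive number.
#' @param channel_labels character vector of unique channel names, one per
#'   column. Defaults to `colnames(data)`.
#' @return An object of class `"mc_recording"`: a list with elements `data`,
#'   `sampling_rate` and `channel_labels`.
#' @examples
#' rec <- recording(matrix(rnorm(512), ncol = 2), 128, c("Cz", "Pz"))
#' n_channels(rec)
#' @export
recording <- function(data, sampling_rate, channel_labels = colnames(data)) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop_invalid("'data' must be a numeric matrix")
  if (anyNA(data) || any(!is.finite(data))) {
    stop_invalid("'data' contains missing or non-finite values")
  }
  if (ncol(data) < 2) stop_invalid("a recording needs at least 2 channels")
  if (nrow(data) <= 10 * ncol(data)) {
    stop_invalid("n_samples must exceed 10 * n_channels (",
                 nrow(data), " samples, ", ncol(data), " channels)")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0) {
    stop_invalid("'sampling_rate' must be a single positive number")
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(ncol(data)))
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != ncol(data)) {
    stop_invalid("label count (", length(channel_labels),
                 ") differs from channel count (", ncol(data), ")")
  }
  if (anyDuplicated(channel_labels)) {
    stop_invalid("channel labels must be unique")
  }
  colnames(data) <- channel_labels
  structure(list(data = data, sampling_rate = sampling_rate,
                 channel_labels = channel_labels),
            class = "mc_recording")
}

#' @rdname recording
#' @param x an `mc_recording` object.
#' @export
n_channels <- function(x) ncol(x$data)

#' @rdname recording
#' @export
n_samples <- function(x) nrow(x$data)

#' @export
print.mc_recording <- function(x, ...) {
  cat(sprintf("<mc_recording> %d samples x %d channels @ %g Hz (%.1f s)\n",
              n_samples(x), n_channels(x), x$sampling_rate,
              n_samples(x) / x$sampling_rate))
  cat("channels:", paste(x$channel_labels, collapse = " "), "\n")
  invisible(x)
}

#' Standard 10-20 montage labels
#'
#' The 21 scalp electrode labels used as default channel names by the
#' synthetic generators and as the universe of the default module partition.
#'
#' @param n optionally return only the first `n` labels.
#' @return character vector of electrode names.
#' @export
montage_1020 <- function(n = NULL) {
  labs <- c("Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
            "C3", "Cz", "C4", "Cp5", "Cp6",
            "P7", "P3", "Pz", "P4", "P8", "O1", "Oz", "O2")
  if (!is.null(n)) {
    if (n > length(labs)) stop_invalid("montage has only ", length(labs),
                                       " labels")
    labs <- labs[seq_len(n)]
  }
  labs
}

#' Directed ground-truth network
#'
#' Known directed edges of a simulated system, used to score estimated
#' adjacencies. Each edge carries the propagation delay in samples and a
#' coupling gain.
#'
#' @param edges data frame with columns `source`, `target`, `delay`, `gain`.
#' @param labels character vector: all channel labels of the companion
#'   recording.
#' @param source_channels labels acting as signal sources.
#' @return object of class `"ground_truth"`.
#' @export
ground_truth <- function(edges, labels,
                         source_channels = unique(edges$source)) {
  edges <- as.data.frame(edges)
  need <- c("source", "target", "delay", "gain")
  if (!all(need %in% names(edges))) {
    stop_invalid("edges needs columns ", paste(need, collapse = ", "))
  }
  if (nrow(edges)) {
    if (any(edges$source == edges$target)) stop_invalid("self-edges not allowed")
    if (any(edges$delay < 0) || any(edges$delay != round(edges$delay))) {
      stop_invalid("delays must be non-negative integers")
    }
    bad <- setdiff(c(edges$source, edges$target), labels)
    if (length(bad)) {
      stop_invalid("edge labels not in recording: ", paste(bad, collapse = ", "))
    }
  }
  structure(list(edges = edges, labels = labels,
                 source_channels = source_channels),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d directed edges over %d channels\n",
              nrow(x$edges), length(x$labels)))
  if (nrow(x$edges)) print(utils::head(x$edges, 10))
  invisible(x)
}

#' Write / read a recording as TSV with a YAML sidecar
#'
#' The TSV has a header row of channel labels and one row per time sample,
#' written at full precision so a written recording reads back bit-identical.
#' Sampling rate (and optionally the generating seed) go to a plain-text YAML
#' sidecar `<path>.meta.yaml`.
#'
#' @param rec an [recording()] object.
#' @param path output file path.
#' @param seed optional integer recorded in the sidecar for provenance.
#' @param extra named list of additional sidecar fields.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, seed = NULL, extra = list()) {
  stopifnot(inherits(rec, "mc_recording"))
  chr <- apply(rec$data, 2, num_chr)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(rec$channel_labels, collapse = "\t"), con)
  writeLines(do.call(paste, c(as.data.frame(chr), sep = "\t")), con)
  meta <- c(list(sampling_rate = rec$sampling_rate), extra)
  if (!is.null(seed)) meta$seed <- seed
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_recording
#' @param sampling_rate rate in Hz; overrides (or substitutes for) the sidecar.
#' @export
read_recording_tsv <- function(path, sampling_rate = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  ncols <- lengths(body)
  if (any(ncols != length(header))) {
    stop_invalid("row(s) ", paste(utils::head(which(ncols != length(header))),
                                  collapse = ", "),
                 " have a column count differing from the header")
  }
  data <- matrix(as.numeric(unlist(body)), ncol = length(header), byrow = TRUE)
  if (is.null(sampling_rate)) {
    side <- paste0(path, ".meta.yaml")
    if (!file.exists(side)) {
      stop_invalid("no sampling rate: pass 'sampling_rate' or provide ", side)
    }
    sampling_rate <- yaml::read_yaml(side)$sampling_rate
    if (is.null(sampling_rate)) stop_invalid("sidecar lacks 'sampling_rate'")
  }
  recording(data, sampling_rate, header)
}

#' Write / read a ground-truth edge list as TSV
#'
#' Columns: `source`, `target`, `delay`, `gain`; a comment header records the
#' full label set so the network round-trips.
#'
#' @param truth a [ground_truth()] object.
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste0("# labels: ", paste(truth$labels, collapse = ",")), con)
  writeLines(paste0("# sources: ",
                    paste(truth$source_channels, collapse = ",")), con)
  writeLines("source\ttarget\tdelay\tgain", con)
  if (nrow(truth$edges)) {
    writeLines(paste(truth$edges$source, truth$edges$target,
                     truth$edges$delay, num_chr(truth$edges$gain),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path)
  grab <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), lines, value = TRUE)
    if (!length(ln)) character() else
      strsplit(sub(paste0("^# ", key, ": "), "", ln[[1]]), ",")[[1]]
  }
  labels <- grab("labels")
  sources <- grab("sources")
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  df$delay <- as.integer(df$delay)
  ground_truth(df, labels, sources)
}
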