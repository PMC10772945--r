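# Normalization and chunking: turn raw reads into the fixed-length
# normalized vectors the classifier consumes.

#' Preprocessing configuration
#'
#' @param chunk_length chunk size in samples; ~4000 samples (~1 s of
#'   acquisition, ~450 bases) is the decision window used throughout.
#' @param skip_samples samples discarded from the read start (0 for
#'   simulated reads; 1000-1500 recommended for real device output, whose
#'   first samples cover the adapter).
#' @param normalization `"median_mad"` (robust, default) or `"zscore"`.
#' @return an object of class `"preprocess_config"`.
#' @export
preprocess_config <- function(chunk_length = 4000L, skip_samples = 0L,
                              normalization = c("median_mad", "zscore")) {
  normalization <- match.arg(normalization)
  if (chunk_length < 1) stop_invalid("chunk_length must be >= 1")
  if (skip_samples < 0) stop_invalid("skip_samples must be >= 0")
  structure(list(chunk_length = as.integer(chunk_length),
                 skip_samples = as.integer(skip_samples),
                 normalization = normalization),
            class = "preprocess_config")
}

degenerate_signal <- function(msg) {
  stop(errorCondition(msg, class = c("nanosieve_degenerate_signal", "error")))
}

#' Normalize a raw signal
#'
#' `median_mad`: `(x - median) / (1.4826 * MAD)`; `zscore`:
#' `(x - mean) / sd`. A signal with zero spread cannot be normalized and
#' raises a degenerate-signal error (callers skip such reads).
#'
#' @param x numeric vector, length >= 2.
#' @param method normalization method.
#' @return normalized vector of the same length.
#' @export
normalize_signal <- function(x, method = c("median_mad", "zscore")) {
  method <- match.arg(method)
  if (length(x) < 2) stop_invalid("signal must have length >= 2")
  if (method == "median_mad") {
    ctr <- median(x)
    s <- 1.4826 * median(abs(x - ctr))
  } else {
    ctr <- mean(x)
    s <- sd(x)
  }
  if (!is.finite(s) || s == 0)
    degenerate_signal("signal has zero spread; cannot normalize")
  (x - ctr) / s
}

#' Cut one normalized chunk from a read
#'
#' Takes samples `[skip_samples, skip_samples + chunk_length)` of the
#' picoamp-converted signal and normalizes them. Reads too short for a
#' full chunk (or with degenerate signal) are skipped, not errors.
#'
#' @param read a `signal_read`.
#' @param cfg a [preprocess_config()].
#' @return an object of class `"signal_chunk"` (fields `values`,
#'   `class_label`, `read_id`, `species`), or `NULL` if skipped.
#' @export
chunk_read <- function(read, cfg = preprocess_config()) {
  n <- length(read$dac)
  if (n < cfg$skip_samples + cfg$chunk_length) return(NULL)
  pa <- signal_pa(read)
  seg <- pa[(cfg$skip_samples + 1L):(cfg$skip_samples + cfg$chunk_length)]
  values <- tryCatch(normalize_signal(seg, cfg$normalization),
                     nanosieve_degenerate_signal = function(e) NULL)
  if (is.null(values)) return(NULL)
  structure(list(values = values, class_label = read$class_label,
                 read_id = read$read_id, species = read$species),
            class = "signal_chunk")
}

#' Build a labelled chunk dataset from reads
#'
#' One chunk per eligible read (the adaptive-sampling use case only ever
#' sees the read start); ineligible reads are counted as skipped. Chunk
#' order is shuffled deterministically by `seed`.
#'
#' @param reads list of `signal_read` objects.
#' @param cfg a [preprocess_config()].
#' @param seed shuffling seed.
#' @return an object of class `"chunk_set"`: a matrix `x` (chunks in
#'   rows), factor `label` with levels host/target, `read_id`, `species`
#'   and skip counts.
#' @export
build_dataset <- function(reads, cfg = preprocess_config(), seed = 1) {
  chunks <- lapply(reads, chunk_read, cfg = cfg)
  keep <- !vapply(chunks, is.null, logical(1))
  n_skipped <- sum(!keep)
  chunks <- chunks[keep]
  labs <- vapply(chunks, `[[`, character(1), "class_label")
  if (!all(c("host", "target") %in% labs)) {
    stop(errorCondition(
      paste0("need at least one eligible read per class; got ",
             sum(labs == "host"), " host / ", sum(labs == "target"),
             " target (", n_skipped, " skipped)"),
      class = c("nanosieve_dataset_imbalance", "error")))
  }
  ord <- with_seed(seed, sample.int(length(chunks)))
  x <- do.call(rbind, lapply(chunks[ord], `[[`, "values"))
  structure(list(
    x = x,
    label = factor(labs[ord], levels = c("host", "target")),
    read_id = vapply(chunks[ord], `[[`, character(1), "read_id"),
    species = vapply(chunks[ord], `[[`, character(1), "species"),
    chunk_length = cfg$chunk_length,
    n_skipped = n_skipped,
    cfg = cfg),
    class = "chunk_set")
}

#' @export
print.chunk_set <- function(x, ...) {
  cat(sprintf("<chunk_set: %d chunks x %d samples (%d host, %d target; %d reads skipped)>\n",
              nrow(x$x), x$chunk_length, sum(x$label == "host"),
              sum(x$label == "target"), x$n_skipped))
  invisible(x)
}

# subset a chunk_set by index, keeping metadata aligned
subset_chunks <- function(data, idx) {
  structure(list(x = data$x[idx, , drop = FALSE],
                 label = data$label[idx],
                 read_id = data$read_id[idx],
                 species = data$species[idx],
                 chunk_length = data$chunk_length,
                 n_skipped = data$n_skipped, cfg = data$cfg),
            class = "chunk_set")
}
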