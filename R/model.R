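# The classifier: a 1D convolutional stem, squeeze-and-excitation channel
# attention before and after a three-block residual stack, global average
# pooling (which removes input-length dependence) and a fully connected
# softmax bi-classifier. Forward/backward and Adam live in src/network.cpp.

#' Classifier architecture hyperparameters
#'
#' Topology is fixed (conv stem -> SE -> 3 residual blocks -> SE -> global
#' average pool -> fully connected softmax); the sizes are tunable. Each
#' residual block is two valid k=3 convolutions with batch normalization
#' and ReLU, downsampling by stride 2, with a 1x1 projection shortcut.
#'
#' @param conv_channels stem output channels.
#' @param conv_kernel stem kernel width in samples.
#' @param conv_stride stem stride.
#' @param se_reduction bottleneck ratio r of the SE blocks; must divide
#'   `conv_channels` and the last residual width.
#' @param residual_channels per-block channel widths (exactly 3 blocks).
#' @param n_classes number of classes (2: host vs target).
#' @param batch_norm batch normalization flag (only `TRUE` is supported).
#' @return an object of class `"classifier_spec"`.
#' @export
classifier_spec <- function(conv_channels = 32L, conv_kernel = 19L,
                            conv_stride = 3L, se_reduction = 4L,
                            residual_channels = c(32L, 64L, 128L),
                            n_classes = 2L, batch_norm = TRUE) {
  if (length(residual_channels) != 3)
    stop_invalid("exactly 3 residual blocks are supported")
  if (conv_channels %% se_reduction != 0 ||
      any(residual_channels %% se_reduction != 0))
    stop_invalid("channel widths must be divisible by se_reduction")
  if (!isTRUE(batch_norm))
    stop_invalid("batch_norm = FALSE is not supported")
  structure(list(conv_channels = as.integer(conv_channels),
                 conv_kernel = as.integer(conv_kernel),
                 conv_stride = as.integer(conv_stride),
                 se_reduction = as.integer(se_reduction),
                 residual_channels = as.integer(residual_channels),
                 n_residual_blocks = 3L,
                 n_classes = as.integer(n_classes),
                 activation = "relu", batch_norm = TRUE),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(sprintf(paste0("<classifier_spec: conv(%d ch, k=%d, s=%d) -> SE(r=%d) -> ",
                     "res[%s] -> SE -> GAP -> FC(%d)>\n"),
              x$conv_channels, x$conv_kernel, x$conv_stride, x$se_reduction,
              paste(x$residual_channels, collapse = ","), x$n_classes))
  invisible(x)
}

# output length of the network's temporal axis for input length T;
# 0 if any convolution would be starved
net_out_len <- function(spec, T) {
  cl <- function(T, k, s) if (T < k) 0L else (T - k) %/% s + 1L
  t <- cl(T, spec$conv_kernel, spec$conv_stride)
  for (i in 1:3) {
    t1 <- cl(t, 3L, 2L)
    t <- if (t1 < 3L) 0L else t1 - 2L
  }
  t
}

#' Minimum admissible input length of a classifier spec
#'
#' The smallest chunk length for which every (valid) convolution in the
#' network still produces at least one output sample.
#'
#' @param spec a [classifier_spec()].
#' @return integer number of samples.
#' @export
min_chunk_length <- function(spec = classifier_spec()) {
  T <- spec$conv_kernel
  while (net_out_len(spec, T) < 1L) T <- T + 1L
  T
}

#' Squeeze-and-excitation block
#'
#' Channel attention on a C x T feature map: squeeze each channel to its
#' temporal mean `s`, compute excitation weights
#' `e = sigmoid(W2 %*% relu(W1 %*% s + b1) + b2)` in `(0,1)^C`, and
#' rescale channel c by `e[c]`.
#'
#' @param features numeric C x T matrix.
#' @param W1 C/r x C matrix; `b1` length C/r; `W2` C x C/r; `b2` length C.
#' @param b1,b2 bias vectors.
#' @return the reweighted C x T matrix.
#' @export
se_block <- function(features, W1, b1, W2, b2) {
  features <- as.matrix(features)
  C <- nrow(features)
  if (ncol(W1) != C || nrow(W2) != C || nrow(W1) != ncol(W2) ||
      length(b1) != nrow(W1) || length(b2) != C)
    stop_invalid("SE weight shapes do not match a ", C, "-channel input")
  cpp_se_block(features, as.matrix(W1), as.numeric(b1),
               as.matrix(W2), as.numeric(b2))
}

count_params <- function(params) {
  trainable <- !grepl("\\.(rmean|rvar)$", names(params))
  sum(vapply(params[trainable], length, integer(1)))
}

# coerce chunk inputs (chunk_set / matrix / list / signal_chunk / vector)
# to a list of numeric vectors
as_chunk_list <- function(newdata) {
  if (inherits(newdata, "chunk_set"))
    return(lapply(seq_len(nrow(newdata$x)), function(i) newdata$x[i, ]))
  if (inherits(newdata, "signal_chunk")) return(list(newdata$values))
  if (is.matrix(newdata))
    return(lapply(seq_len(nrow(newdata)), function(i) newdata[i, ]))
  if (is.list(newdata))
    return(lapply(newdata, function(ch)
      if (inherits(ch, "signal_chunk")) ch$values else as.numeric(ch)))
  if (is.numeric(newdata)) return(list(newdata))
  stop_invalid("cannot interpret newdata as signal chunks")
}

#' Fit the raw-signal classifier
#'
#' Trains the convolutional squeeze-and-excitation network on normalized
#' signal chunks with Adam and cross-entropy loss. Fully reproducible for
#' a fixed `seed` (deterministic initialization and data order).
#'
#' @param x a [build_dataset()] `chunk_set`, or a numeric matrix with one
#'   chunk per row (then `labels` is required).
#' @param labels factor/character vector with levels host/target; ignored
#'   when `x` is a `chunk_set`.
#' @param spec a [classifier_spec()].
#' @param epochs training epochs (accuracy and loss typically saturate
#'   well within 30 on separable data).
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param seed integer seed controlling initialization and shuffling.
#' @param verbose print per-epoch loss/accuracy.
#' @return an object of class `"squiggle_classifier"` with the fitted
#'   parameters, the spec, and per-epoch training curves in `$history`.
#' @seealso [predict.squiggle_classifier()], [classify_batch()]
#' @export
squiggle_classifier <- function(x, labels = NULL, spec = classifier_spec(),
                                epochs = 30L, batch_size = 64L,
                                learning_rate = 1e-3, seed = 1L,
                                verbose = FALSE) {
  if (inherits(x, "chunk_set")) {
    labels <- x$label
    x <- x$x
  }
  if (is.null(labels)) stop_invalid("labels are required")
  if (epochs < 1) stop_invalid("epochs must be >= 1")
  if (learning_rate < 0) stop_invalid("learning_rate must be >= 0")
  labels <- factor(as.character(labels), levels = c("host", "target"))
  if (anyNA(labels)) stop_invalid("labels must be 'host' or 'target'")
  if (length(unique(labels)) < 2) {
    stop(errorCondition("training set contains a single class",
                        class = c("nanosieve_dataset_imbalance", "error")))
  }
  x <- as.matrix(x)
  mcl <- min_chunk_length(spec)
  if (ncol(x) < mcl)
    stop_invalid("chunks of ", ncol(x),
                 " samples are shorter than the minimum input length ", mcl)
  y <- as.integer(labels) - 1L  # host = 0, target = 1
  fit <- with_seed(seed, {
    params <- cpp_init_params(unclass(spec))
    cpp_train(params, unclass(spec), x, y, as.integer(epochs),
              as.integer(batch_size), learning_rate)
  })
  history <- data.frame(epoch = seq_len(epochs),
                        loss = as.numeric(fit$loss),
                        accuracy = as.numeric(fit$accuracy))
  if (verbose) {
    for (i in seq_len(nrow(history)))
      message(sprintf("epoch %d: loss %.4f, accuracy %.3f",
                      i, history$loss[i], history$accuracy[i]))
  }
  structure(list(spec = spec, params = fit$params,
                 classes = c("host", "target"), history = history,
                 training_meta = list(seed = seed, epochs = epochs,
                                      batch_size = batch_size,
                                      learning_rate = learning_rate,
                                      n_train = nrow(x),
                                      final_loss = history$loss[epochs],
                                      final_accuracy = history$accuracy[epochs]),
                 n_params = count_params(fit$params),
                 min_input = mcl,
                 call = match.call()),
            class = "squiggle_classifier")
}

#' Class probabilities for signal chunks
#'
#' The forward pass is deterministic; global average pooling makes the
#' output defined for any admissible input length.
#'
#' @param object a fitted [squiggle_classifier()].
#' @param newdata a `chunk_set`, matrix (chunks in rows), list of numeric
#'   vectors, or a single numeric vector. Lengths may differ between
#'   chunks but each must be at least `object$min_input` samples.
#' @param type `"prob"` for an N x 2 matrix of class probabilities (each
#'   row sums to 1), `"class"` for predicted labels (ties go to target so
#'   that ambiguity never rejects a potentially rare microbial read).
#' @param ... unused.
#' @return matrix of probabilities or factor of labels.
#' @export
predict.squiggle_classifier <- function(object, newdata,
                                        type = c("prob", "class"), ...) {
  type <- match.arg(type)
  chunks <- as_chunk_list(newdata)
  lens <- lengths(chunks)
  if (any(lens < object$min_input))
    stop_invalid("chunk of ", min(lens), " samples is shorter than the ",
                 "minimum input length ", object$min_input)
  p <- cpp_forward(object$params, unclass(object$spec), chunks)
  colnames(p) <- object$classes
  if (type == "prob") return(p)
  factor(ifelse(p[, "target"] >= p[, "host"], "target", "host"),
         levels = object$classes)
}

#' Classify a batch of chunks, timing the call
#'
#' @param model a fitted [squiggle_classifier()].
#' @param chunks anything [predict.squiggle_classifier()] accepts.
#' @return list with `labels`, `probabilities`, and wall-clock timing
#'   (`elapsed_s`, `per_read_s`) for throughput reports.
#' @export
classify_batch <- function(model, chunks) {
  chunks <- as_chunk_list(chunks)
  if (length(chunks) == 0) stop_invalid("empty batch")
  t0 <- proc.time()[["elapsed"]]
  p <- predict(model, chunks, type = "prob")
  elapsed <- proc.time()[["elapsed"]] - t0
  labels <- factor(ifelse(p[, "target"] >= p[, "host"], "target", "host"),
                   levels = model$classes)
  list(labels = labels, probabilities = p, elapsed_s = elapsed,
       per_read_s = elapsed / length(chunks))
}

#' @export
print.squiggle_classifier <- function(x, ...) {
  cat("Raw-signal chunk classifier (conv + SE + residual + GAP + FC)\n")
  print(x$spec)
  cat(sprintf("  parameters: %s   minimum input: %d samples\n",
              format(x$n_params, big.mark = ","), x$min_input))
  n <- nrow(x$history)
  cat(sprintf("  trained %d epoch(s) on %d chunks: loss %.4f, accuracy %.3f\n",
              n, x$training_meta$n_train, x$history$loss[n],
              x$history$accuracy[n]))
  invisible(x)
}

#' @method summary squiggle_classifier
#' @export
summary.squiggle_classifier <- function(object, ...) {
  print(object)
  cat("\nTraining history:\n")
  print(object$history, row.names = FALSE)
  invisible(object)
}

#' @method coef squiggle_classifier
#' @export
coef.squiggle_classifier <- function(object, ...) object$params

#' Plot training curves
#'
#' @param x a fitted [squiggle_classifier()].
#' @param ... passed to [plot()].
#' @method plot squiggle_classifier
#' @export
plot.squiggle_classifier <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$history$epoch, x$history$loss, type = "b", xlab = "epoch",
       ylab = "training loss", ...)
  plot(x$history$epoch, x$history$accuracy, type = "b", xlab = "epoch",
       ylab = "training accuracy", ylim = c(0, 1), ...)
  invisible(x)
}

#' Save / load a fitted classifier
#'
#' A single file with an embedded, versioned spec header.
#'
#' @param model a fitted [squiggle_classifier()].
#' @param path file path.
#' @return `path` (write) or the model (read).
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "squiggle_classifier"))
  payload <- unclass(model)
  payload$format <- "nanosieve-classifier"
  payload$format_version <- 1L
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "nanosieve-classifier"))
    stop_invalid("not a nanosieve classifier file")
  payload$format <- NULL
  payload$format_version <- NULL
  structure(payload, class = "squiggle_classifier")
}
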