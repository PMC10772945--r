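# Evaluation machinery: Mann-Whitney AUC, ROC curves, stratified k-fold
# and leave-one-species-out cross-validation.

#' AUC as the Mann-Whitney probability
#'
#' The probability that a randomly chosen positive outranks a randomly
#' chosen negative, ties counted one half; identical to the trapezoid
#' area under the empirical ROC curve.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1, logical, or a factor whose second level is positive.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop_invalid("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) return(as.integer(labels) - 1L)
  if (is.logical(labels)) return(as.integer(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop_invalid("labels must be 0/1")
  labels
}

#' Empirical ROC curve
#'
#' @inheritParams auc_mann_whitney
#' @return data.frame with columns `fpr`, `tpr`, monotone non-decreasing
#'   from (0,0) to (1,1); tied scores contribute diagonal segments so the
#'   trapezoid area equals [auc_mann_whitney()].
#' @export
roc_points <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop_invalid("both classes must be present to compute a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  keep <- c(s[-length(s)] != s[-1], TRUE)  # last index of each tie group
  tpr <- cumsum(y)[keep] / n1
  fpr <- cumsum(1 - y)[keep] / n0
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

#' Evaluation report for a scored set of chunks
#'
#' Classification uses the target-vs-host rule of the fitted model:
#' target iff `p(target) >= 0.5` (ties toward target). Precision takes
#' target (microbial) as the positive class.
#'
#' @param scores target-class probabilities.
#' @param labels true labels (factor host/target, or 0/1 with 1 = target).
#' @param species optional per-chunk species for per-species recall.
#' @return an object of class `"eval_report"`: accuracy, precision,
#'   `roc_points`, `auc`, a 2x2 `confusion` table (rows = truth), and
#'   `per_species_recall`.
#' @export
eval_report <- function(scores, labels, species = NULL) {
  y <- as_binary_labels(labels)
  pred <- as.integer(scores >= 0.5)
  conf <- table(truth = factor(y, levels = 0:1, labels = c("host", "target")),
                predicted = factor(pred, levels = 0:1,
                                   labels = c("host", "target")))
  tp <- conf["target", "target"]
  fp <- conf["host", "target"]
  roc <- roc_points(scores, y)
  rep <- list(
    accuracy = mean(pred == y),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    confusion = conf,
    roc_points = roc,
    auc = auc_mann_whitney(scores, y),
    n = length(y))
  if (!is.null(species)) {
    rep$per_species_recall <- vapply(split(pred == y, species), mean,
                                     numeric(1))
  }
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: n=%d  accuracy %.3f  precision %s  AUC %.3f>\n",
              x$n, x$accuracy,
              ifelse(is.na(x$precision), "NA", sprintf("%.3f", x$precision)),
              x$auc))
  invisible(x)
}

#' Stratified fold assignment
#'
#' Folds are disjoint, cover all observations, differ in size by at most
#' one overall and within each class.
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed shuffling seed.
#' @return integer fold assignment in `1..k`.
#' @export
cv_folds <- function(labels, k = 5, seed = 1) {
  n <- length(labels)
  if (k < 2) stop_invalid("k must be >= 2")
  folds <- integer(n)
  with_seed(seed, {
    start <- 0L
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
      start <- start + length(idx)
    }
  })
  folds
}

default_scorer <- function(spec, epochs, batch_size, learning_rate) {
  function(train, eval, seed) {
    fit <- squiggle_classifier(train, spec = spec, epochs = epochs,
                               batch_size = batch_size,
                               learning_rate = learning_rate, seed = seed)
    predict(fit, eval, type = "prob")[, "target"]
  }
}

#' k-fold cross-validation
#'
#' The chunk set is evenly divided into `k` stratified folds; each fold
#' serves once as the validation set while the remaining folds form the
#' training set.
#'
#' @param data a [build_dataset()] `chunk_set`.
#' @param k number of folds.
#' @param spec a [classifier_spec()].
#' @param epochs,batch_size,learning_rate training configuration.
#' @param seed seed for fold assignment and per-fold training.
#' @param scorer optional `function(train_set, eval_set, seed)` returning
#'   target-class scores for the evaluation set; replaces model training
#'   (used to inject reference scorers in tests).
#' @return an object of class `"cv_result"`: per-fold [eval_report()]s
#'   and the fold assignment keyed by read id.
#' @export
kfold_cv <- function(data, k = 5, spec = classifier_spec(), epochs = 10L,
                     batch_size = 64L, learning_rate = 1e-3, seed = 1L,
                     scorer = NULL) {
  stopifnot(inherits(data, "chunk_set"))
  if (min(table(data$label)) < k)
    stop_invalid("need at least k chunks per class")
  folds <- cv_folds(data$label, k, seed)
  scorer <- scorer %||% default_scorer(spec, epochs, batch_size, learning_rate)
  reports <- lapply(seq_len(k), function(f) {
    tr <- subset_chunks(data, folds != f)
    ev <- subset_chunks(data, folds == f)
    scores <- scorer(tr, ev, seed + f)
    eval_report(scores, ev$label, ev$species)
  })
  structure(list(mode = "kfold", reports = reports,
                 assignments = stats::setNames(folds, data$read_id)),
            class = "cv_result")
}

#' Leave-one-species-out cross-validation
#'
#' For each target species s, the model is trained with every chunk of s
#' excluded and then asked to classify the held-out species. Because AUC
#' needs both classes, the held-out chunks are mixed with an equal-sized
#' sample of host chunks that was also withheld from training.
#'
#' @inheritParams kfold_cv
#' @return an object of class `"cv_result"` whose `reports` are named by
#'   held-out species.
#' @export
loso_cv <- function(data, spec = classifier_spec(), epochs = 10L,
                    batch_size = 64L, learning_rate = 1e-3, seed = 1L,
                    scorer = NULL) {
  stopifnot(inherits(data, "chunk_set"))
  target_species <- unique(data$species[data$label == "target"])
  if (length(target_species) < 2)
    stop_invalid("leave-one-species-out needs at least 2 target species")
  host_idx <- which(data$label == "host")
  scorer <- scorer %||% default_scorer(spec, epochs, batch_size, learning_rate)
  reports <- list()
  for (i in seq_along(target_species)) {
    s <- target_species[i]
    held <- which(data$species == s & data$label == "target")
    if (length(held) == 0) {
      warning("species '", s, "' has no chunks; skipped")
      next
    }
    n_host_eval <- min(length(held), floor(length(host_idx) / 2))
    host_eval <- with_seed(seed + i,
                           sample(host_idx, n_host_eval))
    ev_idx <- c(held, host_eval)
    tr_idx <- setdiff(seq_along(data$label), ev_idx)
    tr <- subset_chunks(data, tr_idx)
    ev <- subset_chunks(data, ev_idx)
    scores <- scorer(tr, ev, seed + i)
    reports[[s]] <- eval_report(scores, ev$label, ev$species)
  }
  structure(list(mode = "leave_one_species_out", reports = reports,
                 assignments = NULL),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result (%s): %d report(s)>\n", x$mode, length(x$reports)))
  for (nm in seq_along(x$reports)) {
    lbl <- names(x$reports)[nm] %||% sprintf("fold %d", nm)
    if (is.null(names(x$reports)) || !nzchar(lbl)) lbl <- sprintf("fold %d", nm)
    cat("  ", lbl, ": ", sep = "")
    print(x$reports[[nm]])
  }
  invisible(x)
}
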