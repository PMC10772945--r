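# Simulated Read-Until loop: channel partitioning, reject/accept
# semantics, and enrichment statistics. Reads are treated as independent
# events per channel; pore-occupancy economics (re-capture, queuing) are
# deliberately out of scope, so throughput gains are reported, not
# modelled.

#' Adaptive-sampling configuration
#'
#' @param decision_samples raw samples acquired before a decision
#'   (~4000 samples = ~1 s at 4 kHz, ~450 bases).
#' @param latency_samples extra samples acquired between the decision and
#'   the pore-voltage reversal. The default 1000 puts the typical
#'   rejected-read length near 560 bases, in the few-hundred-base regime
#'   a real device leaves behind.
#' @param threshold host-probability above which a read is rejected;
#'   exactly at the threshold the read is accepted, so ambiguity never
#'   discards a potentially rare microbial molecule. A threshold of 1
#'   disables rejection, making the adaptive arm behave like the control.
#' @param adaptive_channels,control_channels disjoint channel ranges; the
#'   default splits a 512-channel flow cell into an adaptive half (1-255)
#'   and an untouched control half (256-512).
#' @param samples_per_base translocation calibration (from the pore
#'   model: sample_rate / bases-per-second).
#' @return an object of class `"adaptive_config"`.
#' @export
adaptive_config <- function(decision_samples = 4000L, latency_samples = 1000L,
                            threshold = 0.5, adaptive_channels = 1:255,
                            control_channels = 256:512,
                            samples_per_base = 4000 / 450) {
  if (decision_samples < 1) stop_invalid("decision_samples must be >= 1")
  if (latency_samples < 0) stop_invalid("latency_samples must be >= 0")
  if (threshold <= 0 || threshold > 1)
    stop_invalid("threshold must be in (0, 1]")
  if (length(intersect(adaptive_channels, control_channels)) > 0)
    stop_invalid("adaptive and control channel ranges must be disjoint")
  if (samples_per_base <= 0) stop_invalid("samples_per_base must be > 0")
  structure(list(decision_samples = as.integer(decision_samples),
                 latency_samples = as.integer(latency_samples),
                 threshold = threshold,
                 adaptive_channels = adaptive_channels,
                 control_channels = control_channels,
                 samples_per_base = samples_per_base),
            class = "adaptive_config")
}

read_full_bases <- function(read, spb) {
  if (!is.null(read$sequence)) return(nchar(read$sequence))
  as.integer(round(length(read$dac) / spb))
}

#' Run the simulated Read-Until loop
#'
#' Control-arm reads pass through untouched. Adaptive-arm reads shorter
#' than the decision window get `no_decision` and full emission.
#' Otherwise the first `decision_samples` are normalized, classified, and
#' the read is either rejected -- emitting only
#' `min(full, round((decision_samples + latency_samples) / samples_per_base))`
#' bases -- or accepted and emitted in full.
#'
#' @param reads list of `signal_read` objects; every channel must fall in
#'   one of the two configured ranges.
#' @param model a fitted [squiggle_classifier()], or a function taking a
#'   matrix of chunks (rows) and returning host probabilities (used to
#'   inject oracle classifiers).
#' @param cfg an [adaptive_config()].
#' @param normalization chunk normalization method.
#' @return a data.frame of per-read outcomes: `read_id`, `arm`,
#'   `decision` (accepted/rejected/no_decision), `emitted_bases`,
#'   `full_length_bases`, `class_label`, `species`.
#' @export
run_adaptive_simulation <- function(reads, model, cfg = adaptive_config(),
                                    normalization = "median_mad") {
  channels <- vapply(reads, `[[`, integer(1), "channel")
  arm <- rep(NA_character_, length(reads))
  arm[channels %in% cfg$adaptive_channels] <- "adaptive"
  arm[channels %in% cfg$control_channels] <- "control"
  if (anyNA(arm))
    stop_invalid("read channel outside both configured channel ranges: ",
                 paste(unique(channels[is.na(arm)]), collapse = ", "))
  full <- vapply(reads, read_full_bases, integer(1),
                 spb = cfg$samples_per_base)
  decision <- rep("no_decision", length(reads))
  emitted <- full
  # gather decision chunks for the adaptive arm
  idx <- which(arm == "adaptive" &
                 vapply(reads, function(r) length(r$dac), integer(1)) >=
                   cfg$decision_samples)
  if (length(idx) > 0) {
    chunks <- vector("list", length(idx))
    usable <- logical(length(idx))
    for (j in seq_along(idx)) {
      r <- reads[[idx[j]]]
      pa <- signal_pa(r)[seq_len(cfg$decision_samples)]
      v <- tryCatch(normalize_signal(pa, normalization),
                    nanosieve_degenerate_signal = function(e) NULL)
      if (!is.null(v)) { chunks[[j]] <- v; usable[j] <- TRUE }
    }
    if (any(usable)) {
      xm <- do.call(rbind, chunks[usable])
      p_host <- if (is.function(model)) {
        model(xm)
      } else {
        predict(model, xm, type = "prob")[, "host"]
      }
      dec_idx <- idx[usable]
      rejected <- p_host > cfg$threshold
      decision[dec_idx] <- ifelse(rejected, "rejected", "accepted")
      trunc_bases <- as.integer(round(
        (cfg$decision_samples + cfg$latency_samples) / cfg$samples_per_base))
      emitted[dec_idx] <- ifelse(rejected, pmin(full[dec_idx], trunc_bases),
                                 full[dec_idx])
    }
  }
  structure(data.frame(
    read_id = vapply(reads, `[[`, character(1), "read_id"),
    arm = arm,
    decision = decision,
    emitted_bases = as.integer(emitted),
    full_length_bases = as.integer(full),
    class_label = vapply(reads, `[[`, character(1), "class_label"),
    species = vapply(reads, `[[`, character(1), "species"),
    stringsAsFactors = FALSE),
    class = c("adaptive_outcomes", "data.frame"))
}

ratio_or_inf <- function(num, den) {
  if (den == 0) Inf else num / den
}

#' Enrichment statistics from adaptive-sampling outcomes
#'
#' Direct tabulation of the outcome table: per-arm/per-class read and
#' base counts, host:microbial ratios among rejected and accepted reads
#' (infinite when no microbial read falls in the group), per-species fold
#' enrichment (adaptive read count / control read count), and read-length
#' summaries.
#'
#' @param outcomes a [run_adaptive_simulation()] data.frame.
#' @return an object of class `"enrichment_report"`.
#' @export
enrichment_report <- function(outcomes) {
  if (nrow(outcomes) == 0) stop_invalid("no outcomes to report on")
  grp <- interaction(outcomes$arm, outcomes$class_label, drop = TRUE)
  by_arm_class <- do.call(rbind, lapply(levels(grp), function(g) {
    sub <- outcomes[grp == g, ]
    data.frame(arm = sub$arm[1], class_label = sub$class_label[1],
               reads = nrow(sub),
               emitted_bases = sum(sub$emitted_bases),
               full_length_bases = sum(sub$full_length_bases))
  }))
  adp <- outcomes[outcomes$arm == "adaptive", ]
  n_rej_host <- sum(adp$decision == "rejected" & adp$class_label == "host")
  n_rej_target <- sum(adp$decision == "rejected" & adp$class_label == "target")
  n_acc_host <- sum(adp$decision == "accepted" & adp$class_label == "host")
  n_acc_target <- sum(adp$decision == "accepted" & adp$class_label == "target")
  decisions <- table(arm = outcomes$arm, decision = outcomes$decision)
  fold <- NULL
  ctl <- outcomes[outcomes$arm == "control", ]
  if (nrow(adp) > 0 && nrow(ctl) > 0) {
    species <- sort(unique(outcomes$species))
    fold <- vapply(species, function(s)
      ratio_or_inf(sum(adp$species == s), sum(ctl$species == s)),
      numeric(1))
  }
  len_summary <- aggregate(emitted_bases ~ arm + class_label + decision,
                           data = outcomes,
                           FUN = function(x) c(n = length(x), mean = mean(x),
                                               median = median(x)))
  microbial_base_fraction <- function(sub) {
    tot <- sum(sub$emitted_bases)
    if (tot == 0) return(NA_real_)
    sum(sub$emitted_bases[sub$class_label == "target"]) / tot
  }
  structure(list(
    by_arm_class = by_arm_class,
    decisions = decisions,
    human_microbial_ratio_rejected = ratio_or_inf(n_rej_host, n_rej_target),
    human_microbial_ratio_accepted = ratio_or_inf(n_acc_host, n_acc_target),
    rejected_counts = c(host = n_rej_host, target = n_rej_target),
    accepted_counts = c(host = n_acc_host, target = n_acc_target),
    fold_enrichment = fold,
    length_summaries = len_summary,
    microbial_base_fraction = c(
      adaptive = if (nrow(adp) > 0) microbial_base_fraction(adp) else NA_real_,
      control = if (nrow(ctl) > 0) microbial_base_fraction(ctl) else NA_real_)),
    class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat("Adaptive-sampling enrichment report\n")
  cat("  reads and emitted bases by arm/class:\n")
  print(x$by_arm_class, row.names = FALSE)
  cat(sprintf("  host:microbial ratio, rejected reads: %s\n",
              format(x$human_microbial_ratio_rejected, digits = 4)))
  cat(sprintf("  host:microbial ratio, accepted reads: %s\n",
              format(x$human_microbial_ratio_accepted, digits = 4)))
  mbf <- x$microbial_base_fraction
  cat(sprintf("  microbial base fraction: adaptive %.4f vs control %.4f\n",
              mbf["adaptive"], mbf["control"]))
  invisible(x)
}

#' Serialize an enrichment report to JSON
#'
#' Infinite ratios (no microbial read in the group) are serialized as
#' `null` with an accompanying `*_defined` flag.
#'
#' @param report an [enrichment_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_json <- function(report, path) {
  num_or_null <- function(x) if (is.finite(x)) x else NA
  out <- list(
    by_arm_class = report$by_arm_class,
    human_microbial_ratio_rejected =
      num_or_null(report$human_microbial_ratio_rejected),
    human_microbial_ratio_rejected_defined =
      is.finite(report$human_microbial_ratio_rejected),
    human_microbial_ratio_accepted =
      num_or_null(report$human_microbial_ratio_accepted),
    human_microbial_ratio_accepted_defined =
      is.finite(report$human_microbial_ratio_accepted),
    fold_enrichment = as.list(report$fold_enrichment),
    microbial_base_fraction = as.list(report$microbial_base_fraction))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Classification-vs-acquisition time budget check
#'
#' Verifies the architectural requirement that classifying a batch of
#' decision windows is faster than acquiring them: per-read latency must
#' stay below `decision_samples / sample_rate` seconds. The measured
#' value is hardware-dependent and is reported, never asserted.
#'
#' @param model a fitted [squiggle_classifier()].
#' @param chunks a batch of decision chunks (conventionally 50).
#' @param sample_rate acquisition rate in Hz.
#' @return list with `pass`, `seconds`, `per_read_s`, `budget_s`.
#' @export
time_budget_check <- function(model, chunks, sample_rate = 4000) {
  chunks <- as_chunk_list(chunks)
  res <- classify_batch(model, chunks)
  budget <- length(chunks[[1]]) / sample_rate
  list(pass = res$per_read_s < budget, seconds = res$elapsed_s,
       per_read_s = res$per_read_s, budget_s = budget)
}

#' Live Read-Until interface contract (stub)
#'
#' Integration with a real device is specified only as a contract: a
#' source yields `(channel, read_id, growing signal)` records and a sink
#' accepts `(channel, read_id, action)` with action `"unblock"` (eject
#' the molecule) or `"stop_receiving"` (sequence to completion). This
#' stub documents the contract and errors if invoked; see
#' [run_adaptive_simulation()] for the simulated loop that implements the
#' same decision semantics.
#'
#' @param source a function yielding `(channel, read_id, signal)` or
#'   `NULL` when the run ends.
#' @param sink a function accepting `(channel, read_id, action)`.
#' @export
read_until_contract <- function(source, sink) {
  stop("live Read-Until device integration is not implemented; ",
       "use run_adaptive_simulation() on simulated reads")
}
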