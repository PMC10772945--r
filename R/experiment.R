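# The package's reference experiment: train the classifier on chunks
# from two compositionally divergent pools, then deplete host reads in a
# simulated host-dominated Read-Until run.

#' Desk-scale host-depletion experiment
#'
#' Runs the full pipeline once, end to end, on simulated data:
#'
#' 1. draw two 6-mer bias vectors (host vs microbial) whose
#'    total-variation distance exceeds 0.5, and generate a reference pool
#'    from each;
#' 2. simulate a balanced training library, cut one normalized
#'    4000-sample chunk per read, and train the classifier on
#'    `n_chunks_per_class` chunks per class (80/20 train/validation
#'    split), reporting held-out AUC and accuracy;
#' 3. simulate a host-dominated library (90% host molar fraction) across
#'    the full 512-channel layout and run the simulated Read-Until loop
#'    with the fitted classifier on the adaptive half (channels 1-255),
#'    leaving channels 256-512 as the control arm;
#' 4. tabulate enrichment: microbial base fractions per arm, the
#'    host:microbial ratio among rejected reads, and rejected-read
#'    lengths.
#'
#' All randomness derives from `seed`.
#'
#' @param seed integer master seed.
#' @param n_chunks_per_class training+validation chunks per class.
#' @param epochs training epochs (loss saturates within a handful on
#'   divergent pools).
#' @param chunk_length decision-window length in samples.
#' @param n_adaptive_reads reads in the host-dominated adaptive run.
#' @param host_molar_ratio molar ratio of host to microbial DNA in the
#'   adaptive-phase library (9 = a 90% host library).
#' @param verbose print progress.
#' @return a list with the fitted model, evaluation numbers
#'   (`heldout_auc`, `heldout_accuracy`), the [enrichment_report()], the
#'   bias total-variation distance, and rejected-read length summaries.
#' @export
host_depletion_experiment <- function(seed = 1, n_chunks_per_class = 2000,
                                      epochs = 5, chunk_length = 4000,
                                      n_adaptive_reads = 2000,
                                      host_molar_ratio = 9,
                                      verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  sub <- with_seed(seed, sample.int(2^31 - 2, 8))

  bias_host <- random_kmer_bias(sub[1])
  bias_target <- random_kmer_bias(sub[2])
  tv <- tv_distance(bias_host, bias_target)
  say("bias total-variation distance: %.3f", tv)

  pool_host <- generate_reference_pool(sub[3], 3, 50000, bias_host, "host")
  pool_target <- generate_reference_pool(sub[4], 3, 50000, bias_target,
                                         "microbe_1")
  model <- default_pore_model(sub[5])

  # training library: balanced classes; short reads are enough since only
  # the first chunk of each read is used
  n_train_reads <- ceiling(2.1 * n_chunks_per_class)
  train_design <- library_design(list(
    list(species = "human", class_label = "host", molar_fmol = 1,
         pool = pool_host),
    list(species = "microbe_1", class_label = "target", molar_fmol = 1,
         pool = pool_target)),
    read_length_dist = list(meanlog = log(1000), sdlog = 0.3,
                            min = 600, max = 5000),
    n_reads = n_train_reads)
  say("simulating %d training reads ...", n_train_reads)
  reads <- simulate_library(train_design, model, seed = sub[6])
  data <- build_dataset(reads, preprocess_config(chunk_length = chunk_length),
                        seed = sub[6])
  # trim to exactly n_chunks_per_class per class
  keep <- unlist(lapply(c("host", "target"), function(cl) {
    idx <- which(data$label == cl)
    if (length(idx) < n_chunks_per_class)
      stop("simulated library produced too few ", cl, " chunks")
    idx[seq_len(n_chunks_per_class)]
  }))
  data <- subset_chunks(data, sort(keep))

  # stratified 80/20 split
  folds <- cv_folds(data$label, k = 5, seed = sub[7])
  train_set <- subset_chunks(data, folds != 5)
  valid_set <- subset_chunks(data, folds == 5)
  say("training on %d chunks, validating on %d ...",
      nrow(train_set$x), nrow(valid_set$x))
  fit <- squiggle_classifier(train_set, epochs = epochs, seed = sub[8],
                             verbose = verbose)
  p <- predict(fit, valid_set, type = "prob")[, "target"]
  heldout_auc <- auc_mann_whitney(p, valid_set$label)
  heldout_accuracy <- mean((p >= 0.5) == (valid_set$label == "target"))
  say("held-out AUC %.4f, accuracy %.4f", heldout_auc, heldout_accuracy)

  # host-dominated adaptive run over the split flow cell
  adaptive_design <- library_design(list(
    list(species = "human", class_label = "host",
         molar_fmol = host_molar_ratio, pool = pool_host),
    list(species = "microbe_1", class_label = "target", molar_fmol = 1,
         pool = pool_target)),
    n_reads = n_adaptive_reads)
  say("simulating %d reads for the adaptive run ...", n_adaptive_reads)
  adaptive_reads <- simulate_library(adaptive_design, model,
                                     seed = sub[6] + 1)
  cfg <- adaptive_config(decision_samples = chunk_length,
                         samples_per_base = model$dwell_mean)
  outcomes <- run_adaptive_simulation(adaptive_reads, fit, cfg)
  report <- enrichment_report(outcomes)
  rejected <- outcomes[outcomes$decision == "rejected", ]

  list(seed = seed,
       bias_tv_distance = tv,
       n_train = nrow(train_set$x), n_validation = nrow(valid_set$x),
       fit = fit,
       heldout_auc = heldout_auc,
       heldout_accuracy = heldout_accuracy,
       outcomes = outcomes,
       report = report,
       rejected_median_bases = if (nrow(rejected) > 0)
         median(rejected$emitted_bases) else NA_real_,
       config = cfg)
}
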