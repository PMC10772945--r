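test_that("training reduces loss on separable data and is reproducible", {
  d <- fixture_dataset(n_reads = 120, seed = 51, chunk_length = 400)
  f1 <- squiggle_classifier(d, spec = tiny_spec(), epochs = 2, seed = 2)
  f2 <- squiggle_classifier(d, spec = tiny_spec(), epochs = 2, seed = 2)
  expect_lt(f1$history$loss[2], f1$history$loss[1])
  expect_equal(f1$history$loss[2], f2$history$loss[2], tolerance = 1e-6)
  expect_identical(f1$params, f2$params)
})

test_that("a zero learning rate leaves parameters at their initialization", {
  d <- fixture_dataset(n_reads = 60, seed = 52, chunk_length = 256)
  sp <- tiny_spec()
  fit <- squiggle_classifier(d, spec = sp, epochs = 1, seed = 3,
                             learning_rate = 0)
  init <- local({set.seed(3); nanosieve:::cpp_init_params(unclass(sp))})
  trainable <- !grepl("rmean|rvar", names(init))
  expect_equal(fit$params[trainable], init[trainable])
})

test_that("single-class training sets are rejected", {
  d <- fixture_dataset(n_reads = 60, seed = 53, chunk_length = 256)
  keep <- d$label == "host"
  expect_error(
    squiggle_classifier(d$x[keep, ], d$label[keep], spec = tiny_spec(),
                        epochs = 1),
    class = "nanosieve_dataset_imbalance")
})

test_that("AUC matches hand-worked values", {
  expect_equal(auc_mann_whitney(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  # 3 of 4 positive-negative pairs correctly ordered
  expect_equal(auc_mann_whitney(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc_mann_whitney(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc_mann_whitney(c(0.1, 0.2), c(1, 1)),
               class = "nanosieve_invalid_argument")
})

test_that("AUC equals the exhaustive pair count and the ROC trapezoid", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    a <- auc_mann_whitney(scores, labels)
    expect_equal(a, auc_pair_oracle(scores, labels), tolerance = 1e-12)
    roc <- roc_points(scores, labels)
    expect_equal(a, nanosieve:::trapezoid_auc(roc), tolerance = 1e-9)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- rnorm(60)
  labels <- sample(0:1, 60, replace = TRUE)
  expect_equal(auc_mann_whitney(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              direction = "<",
                                              quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("ROC curves are monotone from (0,0) to (1,1)", {
  set.seed(8)
  roc <- roc_points(rnorm(50), sample(0:1, 50, replace = TRUE))
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("stratified folds partition the data evenly", {
  for (n in c(20, 57, 100)) {
    for (k in c(2, 5, 7)) {
      labels <- factor(sample(c("host", "target"), n, replace = TRUE,
                              prob = c(0.7, 0.3)))
      folds <- cv_folds(labels, k, seed = n + k)
      expect_equal(length(folds), n)
      expect_true(all(folds %in% 1:k))
      sizes <- tabulate(folds, k)
      expect_lte(diff(range(sizes)), 1)
      for (cl in levels(labels)) {
        cs <- tabulate(folds[labels == cl], k)
        expect_lte(diff(range(cs)), 1)
      }
    }
  }
  # determinism
  labels <- factor(rep(c("host", "target"), 30))
  expect_identical(cv_folds(labels, 5, seed = 1), cv_folds(labels, 5, seed = 1))
})

test_that("k-fold cross-validation validates every chunk exactly once", {
  d <- fixture_dataset(n_reads = 100, seed = 55, chunk_length = 256)
  oracle <- function(train, eval, seed) as.numeric(eval$label == "target")
  cv <- kfold_cv(d, k = 5, scorer = oracle, seed = 9)
  expect_length(cv$reports, 5)
  expect_equal(sum(vapply(cv$reports, `[[`, numeric(1), "n")), nrow(d$x))
  expect_setequal(names(cv$assignments), d$read_id)
  # oracle scores give AUC 1 in every fold
  for (r in cv$reports) expect_equal(r$auc, 1.0)
  # determinism of assignments
  cv2 <- kfold_cv(d, k = 5, scorer = oracle, seed = 9)
  expect_identical(cv$assignments, cv2$assignments)
  expect_error(kfold_cv(d, k = 200, scorer = oracle),
               class = "nanosieve_invalid_argument")
})

test_that("leave-one-species-out holds out the species and its host mates", {
  d <- fixture_dataset(n_reads = 90, seed = 56, chunk_length = 256)
  # relabel target chunks into 3 pseudo-species
  tgt <- which(d$label == "target")
  d$species[tgt] <- paste0("sp", (seq_along(tgt) %% 3) + 1)
  seen <- list()
  oracle <- function(train, eval, seed) {
    seen[[length(seen) + 1]] <<- list(train = train, eval = eval)
    as.numeric(eval$label == "target")
  }
  cv <- loso_cv(d, scorer = oracle, seed = 4)
  expect_setequal(names(cv$reports), c("sp1", "sp2", "sp3"))
  for (i in seq_along(seen)) {
    s <- names(cv$reports)[i]
    expect_false(s %in% seen[[i]]$train$species)
    expect_true(all(seen[[i]]$eval$species[seen[[i]]$eval$label == "target"] == s))
    # host chunks in the evaluation set were not trained on
    expect_length(intersect(seen[[i]]$eval$read_id, seen[[i]]$train$read_id), 0)
  }
  expect_error(loso_cv(fixture_dataset(n_reads = 40, seed = 57,
                                       chunk_length = 256)),
               class = "nanosieve_invalid_argument")
})

test_that("held-out twin species score like their in-training twin", {
  # two target species drawn from the same pool; holding either out
  # should generalize as well as the other
  pools <- fixture_pools(length = 30000)
  m <- fixture_pore_model()
  des <- library_design(list(
    list(species = "human", class_label = "host", molar_fmol = 2,
         pool = pools$host),
    list(species = "twin_a", class_label = "target", molar_fmol = 1,
         pool = pools$target),
    list(species = "twin_b", class_label = "target", molar_fmol = 1,
         pool = pools$target)),
    read_length_dist = list(meanlog = log(300), sdlog = 0.2,
                            min = 240, max = 600),
    n_reads = 1400)
  reads <- simulate_library(des, m, seed = 58)
  d <- build_dataset(reads, preprocess_config(chunk_length = 2000), seed = 58)
  cv <- loso_cv(d, epochs = 6, seed = 6)
  aucs <- vapply(cv$reports, `[[`, numeric(1), "auc")
  expect_gte(min(aucs), 0.8)
  expect_lte(abs(aucs[["twin_a"]] - aucs[["twin_b"]]), 0.12)
})

test_that("a held-out species drawn from the host pool scores near chance", {
  pools <- fixture_pools(length = 30000)
  m <- fixture_pore_model()
  des <- library_design(list(
    list(species = "human", class_label = "host", molar_fmol = 2,
         pool = pools$host),
    list(species = "microbe_real", class_label = "target", molar_fmol = 1,
         pool = pools$target),
    # mislabelled control: "target" species actually drawn from the host pool
    list(species = "microbe_fake", class_label = "target", molar_fmol = 1,
         pool = pools$host)),
    read_length_dist = list(meanlog = log(300), sdlog = 0.2,
                            min = 240, max = 600),
    n_reads = 1400)
  reads <- simulate_library(des, m, seed = 59)
  d <- build_dataset(reads, preprocess_config(chunk_length = 2000), seed = 59)
  cv <- loso_cv(d, epochs = 6, seed = 7)
  expect_gt(cv$reports[["microbe_fake"]]$auc, 0.25)
  expect_lt(cv$reports[["microbe_fake"]]$auc, 0.75)
})
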