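test_that("reference pool generation is deterministic and validates input", {
  p1 <- generate_reference_pool(1, 1, 6, uniform_kmer_bias())
  p2 <- generate_reference_pool(1, 1, 6, uniform_kmer_bias())
  expect_identical(p1$sequences, p2$sequences)
  expect_equal(nchar(p1$sequences), 6)

  expect_error(generate_reference_pool(1, 1, 5, uniform_kmer_bias()),
               class = "nanosieve_invalid_argument")
  expect_error(generate_reference_pool(1, 1, 100, rep(0, 4096)),
               class = "nanosieve_invalid_argument")
  expect_error(generate_reference_pool(1, 1, 100, rep(-1, 4096)),
               class = "nanosieve_invalid_argument")
})

test_that("uniform bias yields near-uniform 6-mer composition", {
  pool <- generate_reference_pool(3, 1, 1e6, uniform_kmer_bias())
  prof <- kmer_profile(pool)
  expect_lt(tv_distance(prof$freqs, uniform_kmer_bias()), 0.05)
})

test_that("divergent bias vectors produce divergent pools", {
  b1 <- random_kmer_bias(31)
  b2 <- random_kmer_bias(32)
  expect_gt(tv_distance(b1, b2), 0.5)
  p1 <- generate_reference_pool(41, 1, 2e5, b1)
  p2 <- generate_reference_pool(42, 1, 2e5, b2)
  f1 <- kmer_profile(p1)$freqs
  f2 <- kmer_profile(p2)$freqs
  cosine <- sum(f1 * f2) / sqrt(sum(f1^2) * sum(f2^2))
  expect_lt(cosine, 0.9)
})

test_that("default pore model is deterministic with distinct in-range levels", {
  m1 <- default_pore_model(seed = 7)
  m2 <- default_pore_model(seed = 7)
  expect_identical(m1$level_mean, m2$level_mean)
  expect_gte(min(m1$level_mean), 60)
  expect_lte(max(m1$level_mean), 120)
  expect_equal(anyDuplicated(m1$level_mean), 0)
  expect_equal(length(m1$level_mean), 4096)
})

test_that("squiggle sample count follows the dwell arithmetic", {
  m <- fixture_pore_model()
  m$dwell_mean <- 10; m$dwell_sd <- 0
  seqn <- generate_reference_pool(8, 1, 450, uniform_kmer_bias())$sequences[1]
  r <- sequence_to_squiggle(seqn, m, seed = 1)
  expect_equal(length(r$dac), (450 - 5) * 10)
  # base-to-sample map covers the signal exactly once, in order
  bts <- r$base_to_sample
  expect_equal(unname(bts[1, "first_sample"]), 1)
  expect_equal(unname(bts[nrow(bts), "last_sample"]), length(r$dac))
  expect_true(all(bts[-1, "first_sample"] == head(bts[, "last_sample"], -1) + 1))
})

test_that("zero-noise squiggle reconstructs the pore model sample-by-sample", {
  m <- fixture_pore_model()
  m$level_sd <- rep(0, 4096); m$dwell_mean <- 10; m$dwell_sd <- 0
  seqn <- generate_reference_pool(9, 1, 60, uniform_kmer_bias())$sequences[1]
  r <- sequence_to_squiggle(seqn, m, seed = 1)
  codes <- nanosieve:::dna_to_codes(seqn)
  idx <- nanosieve:::window_kmer_index(codes, 6)
  expected_dac <- nanosieve:::pa_to_dac(rep(m$level_mean[idx], each = 10), m)
  expect_identical(r$dac, expected_dac)
})

test_that("single-window squiggle mean tracks its level within standard error", {
  m <- fixture_pore_model()
  m$level_mean[] <- 85; m$level_sd <- rep(1, 4096)
  m$dwell_mean <- 10; m$dwell_sd <- 0
  for (s in 1:5) {
    r <- sequence_to_squiggle("ACGTAC", m, seed = s)
    expect_equal(length(r$dac), 10)
    expect_lt(abs(mean(signal_pa(r)) - 85), 3 / sqrt(10) + 0.09)
  }
})

test_that("squiggles reject invalid sequences", {
  m <- fixture_pore_model()
  expect_error(sequence_to_squiggle("ACGTNN", m, seed = 1),
               class = "nanosieve_invalid_argument")
  expect_error(sequence_to_squiggle("ACGT", m, seed = 1),
               class = "nanosieve_invalid_argument")
})

test_that("library composition converges to molar fractions", {
  pools <- fixture_pools(n_sequences = 1, length = 5000)
  m <- fixture_pore_model()
  comps <- c(lapply(1:6, function(i)
    list(species = paste0("microbe_", i), class_label = "target",
         molar_fmol = 6, pool = pools$target)),
    list(list(species = "microbe_7", class_label = "target",
              molar_fmol = 3, pool = pools$target),
         list(species = "human", class_label = "host",
              molar_fmol = 250, pool = pools$host)))
  des <- library_design(comps, read_length_dist = list(
    meanlog = log(150), sdlog = 0.2, min = 100, max = 400), n_reads = 4000)
  reads <- simulate_library(des, m, seed = 6)
  host_frac_expected <- 250 / (6 * 6 + 3 + 250)
  host_frac <- mean(vapply(reads, `[[`, character(1), "class_label") == "host")
  se <- sqrt(host_frac_expected * (1 - host_frac_expected) / 4000)
  expect_lt(abs(host_frac - host_frac_expected), 3 * se)
})

test_that("single-component libraries carry one label and are reproducible", {
  pools <- fixture_pools(n_sequences = 1, length = 3000)
  m <- fixture_pore_model()
  des <- library_design(list(list(species = "m", class_label = "target",
                                  molar_fmol = 1, pool = pools$target)),
                        read_length_dist = list(meanlog = log(120), sdlog = 0.1,
                                                min = 100, max = 200),
                        n_reads = 20)
  r1 <- simulate_library(des, m, seed = 2)
  r2 <- simulate_library(des, m, seed = 2)
  expect_true(all(vapply(r1, `[[`, character(1), "class_label") == "target"))
  expect_identical(lapply(r1, `[[`, "dac"), lapply(r2, `[[`, "dac"))
})

test_that("molar fractions match the mock-community worked example", {
  f <- molar_fractions(c(rep(6, 6), 3, 250))
  expect_identical(f[1:6], rep(2.08, 6))
  expect_identical(f[7], 1.04)
  expect_identical(f[8], 86.51)
  expect_identical(molar_fractions(c(1, 1)), c(50, 50))
  expect_error(molar_fractions(c(1, 0)),
               class = "nanosieve_invalid_argument")
  expect_error(molar_fractions(c(1, -2)),
               class = "nanosieve_invalid_argument")
})

test_that("sigtab directories round-trip reads and ground truth", {
  reads <- fixture_reads(n_reads = 5, seed = 11)
  dir <- withr::local_tempdir()
  write_sigtab(reads, dir)
  expect_true(file.exists(file.path(dir, "reads.tsv")))
  expect_true(file.exists(file.path(dir, "signals.bin")))
  back <- read_sigtab(dir)
  expect_equal(length(back), length(reads))
  for (i in seq_along(reads)) {
    expect_identical(back[[i]]$dac, reads[[i]]$dac)
    expect_identical(back[[i]]$read_id, reads[[i]]$read_id)
    expect_identical(back[[i]]$class_label, reads[[i]]$class_label)
    expect_identical(back[[i]]$channel, reads[[i]]$channel)
    expect_equal(unname(back[[i]]$base_to_sample),
                 unname(reads[[i]]$base_to_sample))
  }
})

test_that("reference pools round-trip through FASTA", {
  pool <- fixture_pools(n_sequences = 3, length = 500)$host
  path <- withr::local_tempfile(fileext = ".fasta")
  write_pool_fasta(pool, path)
  back <- read_pool_fasta(path, name = "host")
  expect_identical(back$sequences, pool$sequences)
})
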