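# Shared fixtures: small divergent sequence pools, a pore model, and
# chunk datasets sized for fast tests. Everything is generated in code
# under fixed seeds.

tiny_spec <- function() {
  classifier_spec(conv_channels = 8L, conv_kernel = 9L, conv_stride = 3L,
                  se_reduction = 4L, residual_channels = c(8L, 8L, 16L))
}

fixture_pore_model <- function() default_pore_model(seed = 7)

# host and target pools with strongly divergent 6-mer composition
fixture_pools <- function(mix = 1, seed_host = 101, seed_target = 202,
                          n_sequences = 2, length = 20000) {
  list(
    host = generate_reference_pool(
      seed_host, n_sequences, length,
      blend_kmer_bias(random_kmer_bias(seed_host), mix), "host"),
    target = generate_reference_pool(
      seed_target, n_sequences, length,
      blend_kmer_bias(random_kmer_bias(seed_target), mix), "microbe"))
}

# balanced two-component library of short reads
fixture_reads <- function(n_reads = 200, seed = 5, pools = fixture_pools(),
                          model = fixture_pore_model(),
                          host_fmol = 1, target_fmol = 1,
                          len_median = 300, len_min = 150, len_max = 900) {
  des <- library_design(
    list(list(species = "human", class_label = "host",
              molar_fmol = host_fmol, pool = pools$host),
         list(species = "microbe_1", class_label = "target",
              molar_fmol = target_fmol, pool = pools$target)),
    read_length_dist = list(meanlog = log(len_median), sdlog = 0.3,
                            min = len_min, max = len_max),
    n_reads = n_reads)
  simulate_library(des, model, seed = seed)
}

# small labelled chunk dataset ready for training (chunk_length 512)
fixture_dataset <- function(n_reads = 200, seed = 5,
                            chunk_length = 512) {
  reads <- fixture_reads(n_reads = n_reads, seed = seed)
  build_dataset(reads, preprocess_config(chunk_length = chunk_length),
                seed = seed)
}

# hand-rolled SE block arithmetic, independent of the C++ path
se_oracle <- function(x, W1, b1, W2, b2) {
  s <- rowMeans(x)
  h <- pmax(W1 %*% s + b1, 0)
  e <- 1 / (1 + exp(-(W2 %*% h + b2)))
  x * as.numeric(e)
}

# exhaustive Mann-Whitney pair enumeration, ties counted one half
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
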