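# Squiggle simulator: reference pools with controlled 6-mer composition,
# a per-k-mer Gaussian pore model, and labelled reads with ground-truth
# base-to-sample maps.

#' Uniform k-mer sampling bias
#'
#' @param k k-mer size.
#' @return a `4^k` vector summing to 1.
#' @export
uniform_kmer_bias <- function(k = 6) {
  rep(1 / 4^k, 4^k)
}

#' Random k-mer sampling bias
#'
#' Draws Dirichlet-like weights (normalized gamma variates). Smaller
#' `concentration` gives a spikier, more divergent composition; two
#' independent draws at the default concentration are typically more than
#' 0.5 apart in total-variation distance, emulating the gulf between host
#' and microbial 6-mer spectra.
#'
#' @param seed integer seed; the caller's RNG state is untouched.
#' @param k k-mer size.
#' @param concentration gamma shape parameter (> 0).
#' @return a `4^k` vector summing to 1.
#' @export
random_kmer_bias <- function(seed, k = 6, concentration = 0.3) {
  stopifnot(concentration > 0)
  with_seed(seed, {
    w <- rgamma(4^k, shape = concentration, rate = 1)
    w <- w + 1e-12  # keep every k-mer reachable
    w / sum(w)
  })
}

#' Blend a k-mer bias with the uniform distribution
#'
#' `mix = 0` gives uniform composition, `mix = 1` returns `bias`
#' unchanged; intermediate values interpolate linearly, giving a single
#' dial for how far a sequence pool sits from uniform composition.
#'
#' @param bias a `4^k` probability vector.
#' @param mix mixing weight in `[0, 1]`.
#' @return a `4^k` probability vector.
#' @export
blend_kmer_bias <- function(bias, mix) {
  stopifnot(mix >= 0, mix <= 1)
  k <- as.integer(round(log(length(bias), 4)))
  (1 - mix) * uniform_kmer_bias(k) + mix * bias / sum(bias)
}

validate_bias <- function(kmer_bias, k = 6) {
  if (length(kmer_bias) != 4^k)
    stop_invalid("kmer_bias must have length ", 4^k)
  if (any(kmer_bias < 0) || any(!is.finite(kmer_bias)))
    stop_invalid("kmer_bias entries must be finite and >= 0")
  s <- sum(kmer_bias)
  if (s <= 0) stop_invalid("kmer_bias must have positive total weight")
  kmer_bias / s
}

#' Reference pool constructor
#'
#' A named pool of DNA sequences together with the 6-mer sampling bias
#' used to generate them (or `NULL` for pools loaded from FASTA).
#'
#' @param name text label, e.g. `"host"` or `"microbe_1"`.
#' @param sequences character vector of DNA strings over A/C/G/T.
#' @param kmer_bias optional `4^6` probability vector.
#' @return an object of class `"reference_pool"`.
#' @export
reference_pool <- function(name, sequences, kmer_bias = NULL) {
  if (length(sequences) == 0 || any(!nzchar(sequences)))
    stop_invalid("all sequences must be non-empty")
  if (!is.null(kmer_bias)) kmer_bias <- validate_bias(kmer_bias)
  structure(list(name = name, sequences = as.character(sequences),
                 kmer_bias = kmer_bias),
            class = "reference_pool")
}

#' @export
print.reference_pool <- function(x, ...) {
  cat(sprintf("<reference_pool '%s': %d sequence(s), %s total bases>\n",
              x$name, length(x$sequences),
              format(sum(nchar(x$sequences)), big.mark = ",")))
  invisible(x)
}

#' Generate a reference pool by a 5th-order Markov chain
#'
#' Sequences are sampled base by base from the conditional distribution
#' `P(next base | previous 5 bases)` implied by `kmer_bias` read as a joint
#' 6-mer distribution, so the stationary 6-mer composition of long
#' sequences approximates `kmer_bias`. The initial 5-mer is drawn from the
#' bias's 5-mer marginal.
#'
#' @param seed integer seed; generation is bit-for-bit reproducible.
#' @param n_sequences number of sequences.
#' @param length length of each sequence in bases (>= 6).
#' @param kmer_bias `4^6` sampling-weight vector (normalized internally).
#' @param name pool label.
#' @return a [reference_pool()].
#' @export
generate_reference_pool <- function(seed, n_sequences, length,
                                    kmer_bias = uniform_kmer_bias(),
                                    name = "pool") {
  if (length < 6) stop_invalid("sequence length must be >= 6")
  kmer_bias <- validate_bias(kmer_bias)
  k <- 6L
  n_states <- 4L^(k - 1L)
  joint <- matrix(kmer_bias, nrow = 4L)     # rows: next base, cols: 5-mer prefix
  marg5 <- colSums(joint)
  trans <- t(joint)                          # n_states x 4
  zero <- rowSums(trans) <= 0
  trans[zero, ] <- 1
  trans <- trans / rowSums(trans)
  trans_cum <- t(apply(trans, 1, cumsum))
  with_seed(seed, {
    seqs <- vapply(seq_len(n_sequences), function(i) {
      init_state <- sample.int(n_states, 1, prob = marg5 + 1e-300) - 1L
      init_codes <- (init_state %/% 4L^((k - 2L):0)) %% 4L
      codes <- cpp_markov_chain(as.integer(length), trans_cum,
                                as.integer(init_codes))
      codes_to_dna(codes)
    }, character(1))
    reference_pool(name, seqs, kmer_bias)
  })
}

#' k-mer pore model
#'
#' Maps each k-mer (the ~6 bases residing in the pore at measurement time)
#' to a Gaussian current level, plus a dwell-time distribution linking
#' bases to sample counts and DAC conversion constants. Picoamp
#' conversion is `pA = (dac + offset) * range / digitisation`.
#'
#' @param k k-mer size.
#' @param level_mean `4^k` vector of mean currents (pA).
#' @param level_sd per-k-mer current SD (pA, > 0); recycled if scalar.
#' @param dwell_mean mean samples per base (default 4000 Hz / 450 b/s).
#' @param dwell_sd SD of samples per base.
#' @param sample_rate acquisition rate in Hz.
#' @param digitisation,offset,range DAC conversion constants.
#' @return an object of class `"pore_model"`.
#' @export
pore_model <- function(k = 6, level_mean, level_sd = 1.5,
                       dwell_mean = 4000 / 450, dwell_sd = 1.5,
                       sample_rate = 4000, digitisation = 8192,
                       offset = 0, range = 1400) {
  if (length(level_mean) != 4^k)
    stop_invalid("level_mean must have length ", 4^k)
  level_sd <- rep_len(level_sd, 4^k)
  if (any(level_sd < 0)) stop_invalid("level_sd must be >= 0")
  if (dwell_mean <= 0) stop_invalid("dwell_mean must be > 0")
  structure(list(k = as.integer(k), level_mean = level_mean,
                 level_sd = level_sd, dwell_mean = dwell_mean,
                 dwell_sd = dwell_sd, sample_rate = sample_rate,
                 digitisation = digitisation, offset = offset,
                 range = range),
            class = "pore_model")
}

#' @export
print.pore_model <- function(x, ...) {
  cat(sprintf(paste0("<pore_model k=%d: levels %.1f-%.1f pA, ",
                     "%.2f samples/base @ %g Hz>\n"),
              x$k, min(x$level_mean), max(x$level_mean),
              x$dwell_mean, x$sample_rate))
  invisible(x)
}

#' Default pore model with distinct per-6-mer levels
#'
#' Level means are drawn uniformly (without ties) from 60-120 pA, the
#' working range of a MinION-like device, so that 6-mer identity alone
#' determines the expected current -- the premise that makes raw-signal
#' classification possible.
#'
#' @param seed integer seed.
#' @return a [pore_model()].
#' @export
default_pore_model <- function(seed = 1) {
  with_seed(seed, {
    lv <- runif(4096, 60, 120)
    while (anyDuplicated(lv)) lv <- runif(4096, 60, 120)
    pore_model(k = 6, level_mean = lv, level_sd = 1.5)
  })
}

pa_to_dac <- function(pa, model) {
  dac <- round(pa * model$digitisation / model$range - model$offset)
  as.integer(pmin(pmax(dac, -32768), 32767))
}

#' Convert a read's raw DAC samples to picoamps
#'
#' @param read a [sequence_to_squiggle()] read.
#' @return numeric vector of currents in pA.
#' @export
signal_pa <- function(read) {
  (read$dac + read$offset) * read$range / read$digitisation
}

#' Simulate the squiggle of one DNA sequence
#'
#' For each k-mer window i, a dwell `d_i ~ round(N(dwell_mean, dwell_sd))`
#' clipped to >= 1 sample is drawn, then `d_i` current samples from
#' `N(level_mean[kmer_i], level_sd[kmer_i])`, converted to DAC units. The
#' window-to-sample map is recorded as ground truth.
#'
#' @param sequence DNA string over A/C/G/T, length >= k.
#' @param model a [pore_model()].
#' @param seed integer seed, or `NULL` to draw from the current RNG state.
#' @param read_id,species,class_label,channel read metadata;
#'   `class_label` is `"host"` or `"target"`.
#' @return an object of class `"signal_read"` with fields `dac`,
#'   `sequence`, `base_to_sample` (columns base_index, first_sample,
#'   last_sample; 1-based, contiguous, jointly covering the signal) and
#'   the DAC conversion constants.
#' @export
sequence_to_squiggle <- function(sequence, model, seed = NULL,
                                 read_id = "read_1", species = "unknown",
                                 class_label = "target", channel = 1L) {
  codes <- dna_to_codes(sequence)
  if (anyNA(codes))
    stop_invalid("sequence contains non-ACGT characters")
  if (length(codes) < model$k)
    stop_invalid("sequence shorter than k = ", model$k)
  with_seed(seed, {
    idx <- window_kmer_index(codes, model$k)
    nw <- length(idx)
    dwell <- pmax(1, round(rnorm(nw, model$dwell_mean, model$dwell_sd)))
    per_sample <- rep.int(idx, dwell)
    pa <- rnorm(length(per_sample),
                mean = model$level_mean[per_sample],
                sd = model$level_sd[per_sample])
    last <- cumsum(dwell)
    structure(list(
      read_id = read_id, species = species, class_label = class_label,
      dac = pa_to_dac(pa, model), channel = as.integer(channel),
      sequence = sequence,
      base_to_sample = cbind(base_index = seq_len(nw),
                             first_sample = last - dwell + 1L,
                             last_sample = last),
      digitisation = model$digitisation, offset = model$offset,
      range = model$range, sample_rate = model$sample_rate,
      samples_per_base = model$dwell_mean),
      class = "signal_read")
  })
}

#' @export
print.signal_read <- function(x, ...) {
  cat(sprintf("<signal_read %s [%s/%s] ch%d: %d samples, %d bases>\n",
              x$read_id, x$species, x$class_label, x$channel,
              length(x$dac), nchar(x$sequence %||% "")))
  invisible(x)
}

#' Library design for a mock community
#'
#' Describes the molar composition of a sequencing library: which species
#' it contains, their class (host vs target), their molar amounts in fmol
#' and source reference pools, plus the read-length distribution.
#'
#' @param components a list of lists with fields `species`, `class_label`,
#'   `molar_fmol`, `pool` (a [reference_pool()]).
#' @param read_length_dist log-normal read-length parameters:
#'   `meanlog`, `sdlog`, and truncation bounds `min`, `max` (bases).
#'   Default: median 3 kb, sigma 0.5 on the log scale, truncated to
#'   500 b - 50 kb.
#' @param n_reads number of reads to simulate.
#' @return an object of class `"library_design"`.
#' @export
library_design <- function(components,
                           read_length_dist = list(meanlog = log(3000),
                                                   sdlog = 0.5,
                                                   min = 500, max = 50000),
                           n_reads = 1000L) {
  if (length(components) == 0) stop_invalid("design has no components")
  species <- vapply(components, `[[`, character(1), "species")
  if (anyDuplicated(species)) stop_invalid("component species must be unique")
  amounts <- vapply(components, `[[`, numeric(1), "molar_fmol")
  if (any(amounts <= 0)) stop_invalid("molar amounts must be > 0")
  if (n_reads < length(components))
    stop_invalid("n_reads must be >= number of components")
  structure(list(components = components,
                 read_length_dist = read_length_dist,
                 n_reads = as.integer(n_reads)),
            class = "library_design")
}

#' Molar fractions of library components
#'
#' @param amounts molar amounts (fmol), all > 0.
#' @return percentages summing to ~100, reported to two decimals.
#' @examples
#' # a host-dominated mock community: 6 species at 6 fmol, one at 3 fmol,
#' # host at 250 fmol
#' molar_fractions(c(rep(6, 6), 3, 250))
#' @export
molar_fractions <- function(amounts) {
  if (length(amounts) == 0 || any(!is.finite(amounts)) || any(amounts <= 0))
    stop_invalid("all molar amounts must be finite and > 0")
  round(100 * amounts / sum(amounts), 2)
}

#' Simulate a labelled squiggle library
#'
#' Each read's source component is drawn with probability equal to its
#' molar fraction; a fragment of a uniformly chosen reference sequence is
#' excised at the drawn read length and converted to a squiggle; channels
#' are assigned uniformly over 1-512.
#'
#' @param design a [library_design()].
#' @param model a [pore_model()].
#' @param seed integer seed.
#' @param channels channel range to assign reads to.
#' @return list of `signal_read` objects.
#' @export
simulate_library <- function(design, model, seed = 1, channels = 1:512) {
  stopifnot(inherits(design, "library_design"), inherits(model, "pore_model"))
  amounts <- vapply(design$components, `[[`, numeric(1), "molar_fmol")
  frac <- amounts / sum(amounts)
  rld <- design$read_length_dist
  with_seed(seed, {
    comp_idx <- sample.int(length(frac), design$n_reads, replace = TRUE,
                           prob = frac)
    lens <- round(rlnorm(design$n_reads, rld$meanlog, rld$sdlog))
    lens <- pmin(pmax(lens, rld$min), rld$max)
    chan <- sample(channels, design$n_reads, replace = TRUE)
    lapply(seq_len(design$n_reads), function(i) {
      comp <- design$components[[comp_idx[i]]]
      refs <- comp$pool$sequences
      ref <- refs[[sample.int(length(refs), 1)]]
      len <- min(lens[i], nchar(ref))
      start <- sample.int(nchar(ref) - len + 1L, 1)
      frag <- substr(ref, start, start + len - 1L)
      sequence_to_squiggle(frag, model, seed = NULL,
                           read_id = sprintf("read_%06d", i),
                           species = comp$species,
                           class_label = comp$class_label,
                           channel = chan[i])
    })
  })
}
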