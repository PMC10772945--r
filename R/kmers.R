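# 6-mer composition and per-k-mer signal analysis: the compositional
# rationale for classifying reads from raw current. Host and microbial
# genomes differ in 6-mer spectra, and each 6-mer carries a distinct
# current level, so composition differences are visible in the squiggle.

#' k-mer composition profile
#'
#' Counts every length-k window of the given strand. Windows containing
#' ambiguous (non-ACGT) bases are excluded from the counts and tallied
#' separately.
#'
#' @param sequences character vector of DNA strings, or a
#'   [reference_pool()].
#' @param k k-mer size (>= 1).
#' @param reverse_complement also count the reverse-complement strand.
#' @return an object of class `"kmer_profile"`: named `counts` (length
#'   `4^k`, lexicographic order), normalized `freqs`, and the number of
#'   ambiguous windows.
#' @export
kmer_profile <- function(sequences, k = 6, reverse_complement = FALSE) {
  if (inherits(sequences, "reference_pool")) sequences <- sequences$sequences
  if (k < 1) stop_invalid("k must be >= 1")
  x <- Biostrings::DNAStringSet(sequences)
  if (reverse_complement) x <- c(x, Biostrings::reverseComplement(x))
  counts <- colSums(Biostrings::oligonucleotideFrequency(x, width = k))
  widths <- Biostrings::width(x)
  n_windows <- sum(pmax(widths - k + 1L, 0L))
  structure(list(k = as.integer(k), counts = counts,
                 freqs = if (sum(counts) > 0) counts / sum(counts)
                         else counts,
                 n_ambiguous = n_windows - sum(counts)),
            class = "kmer_profile")
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat(sprintf("<kmer_profile k=%d: %s windows counted (%d ambiguous)>\n",
              x$k, format(sum(x$counts), big.mark = ","), x$n_ambiguous))
  invisible(x)
}

#' Combine k-mer profiles
#'
#' Profiles are additive: the profile of a concatenated sequence set is
#' the sum of the individual profiles.
#'
#' @param ... `kmer_profile` objects with identical k.
#' @return the combined `kmer_profile`.
#' @export
combine_profiles <- function(...) {
  ps <- list(...)
  ks <- vapply(ps, `[[`, integer(1), "k")
  if (length(unique(ks)) != 1) stop_invalid("profiles have different k")
  counts <- Reduce(`+`, lapply(ps, `[[`, "counts"))
  structure(list(k = ks[1], counts = counts,
                 freqs = if (sum(counts) > 0) counts / sum(counts)
                         else counts,
                 n_ambiguous = sum(vapply(ps, `[[`, numeric(1),
                                          "n_ambiguous"))),
            class = "kmer_profile")
}

#' Top differentially enriched k-mers
#'
#' Ranks k-mers by `log2((freq_a * 4^k + p) / (freq_b * 4^k + p))` -- the
#' log fold change of frequency relative to uniform, with pseudocount `p`
#' on the `4^k`-scaled frequencies to avoid division by zero. Ties break
#' lexicographically. Swapping the two profiles reverses the ranking, so
#' the bottom of one call is the top of the swapped call.
#'
#' @param profile_a,profile_b `kmer_profile` objects with the same k.
#' @param n how many k-mers to return.
#' @param pseudocount pseudocount `p` (default 1).
#' @return data.frame with columns `kmer`, `score`, `freq_a`, `freq_b`,
#'   sorted by decreasing score.
#' @export
top_enriched <- function(profile_a, profile_b, n = 10, pseudocount = 1) {
  if (profile_a$k != profile_b$k)
    stop_invalid("profiles have different k")
  scale <- 4^profile_a$k
  score <- log2((profile_a$freqs * scale + pseudocount) /
                  (profile_b$freqs * scale + pseudocount))
  kmers <- names(profile_a$counts)
  ord <- order(-score, kmers)
  head(data.frame(kmer = kmers[ord], score = score[ord],
                  freq_a = profile_a$freqs[ord],
                  freq_b = profile_b$freqs[ord],
                  row.names = NULL), n)
}

#' Per-k-mer signal summaries from ground-truthed reads
#'
#' Pools, for each k-mer, all current samples attributed to that k-mer's
#' windows by the simulator's base-to-sample map, and summarizes each
#' k-mer by mean current, current SD, mean dwell, and a fixed-width
#' resampled level trace (each occurrence linearly resampled to `w`
#' points, then averaged). Real-read segmentation is out of scope: reads
#' must carry ground truth.
#'
#' @param reads list of `signal_read` objects with `base_to_sample` truth
#'   and sequences.
#' @param k k-mer size of the pore model that generated the reads.
#' @param w width of the resampled level trace.
#' @param min_occurrences drop k-mers observed fewer times than this.
#' @return an object of class `"kmer_signal_matrix"`: a numeric matrix
#'   with one row per retained k-mer and columns `mean_current`,
#'   `sd_current`, `mean_dwell`, `trace_1..w`; attribute `n_occurrences`.
#' @export
extract_kmer_signals <- function(reads, k = 6, w = 8, min_occurrences = 5) {
  ok <- vapply(reads, function(r)
    !is.null(r$base_to_sample) && !is.null(r$sequence), logical(1))
  if (!all(ok))
    stop_invalid("all reads must carry base-to-sample ground truth ",
                 "(real-read segmentation is not provided)")
  acc_n <- acc_sum <- acc_sumsq <- acc_dwell <- acc_occ <- numeric(4^k)
  acc_trace <- matrix(0, nrow = 4^k, ncol = w)
  grid <- seq(0, 1, length.out = w)
  for (r in reads) {
    codes <- dna_to_codes(r$sequence)
    idx <- window_kmer_index(codes, k)
    pa <- signal_pa(r)
    bts <- r$base_to_sample
    for (j in seq_along(idx)) {
      ki <- idx[j]
      s <- pa[bts[j, "first_sample"]:bts[j, "last_sample"]]
      d <- length(s)
      acc_n[ki] <- acc_n[ki] + d
      acc_sum[ki] <- acc_sum[ki] + sum(s)
      acc_sumsq[ki] <- acc_sumsq[ki] + sum(s^2)
      acc_dwell[ki] <- acc_dwell[ki] + d
      acc_occ[ki] <- acc_occ[ki] + 1
      tr <- if (d == 1) rep(s, w)
            else approx(seq(0, 1, length.out = d), s, xout = grid)$y
      acc_trace[ki, ] <- acc_trace[ki, ] + tr
    }
  }
  keep <- which(acc_occ >= min_occurrences)
  if (length(keep) == 0) {
    m <- matrix(numeric(0), nrow = 0,
                ncol = 3 + w,
                dimnames = list(NULL, c("mean_current", "sd_current",
                                        "mean_dwell",
                                        paste0("trace_", seq_len(w)))))
    return(structure(m, n_occurrences = numeric(0),
                     class = c("kmer_signal_matrix", "matrix", "array")))
  }
  mean_cur <- acc_sum[keep] / acc_n[keep]
  var_cur <- pmax(acc_sumsq[keep] / acc_n[keep] - mean_cur^2, 0)
  m <- cbind(mean_current = mean_cur,
             sd_current = sqrt(var_cur),
             mean_dwell = acc_dwell[keep] / acc_occ[keep],
             acc_trace[keep, , drop = FALSE] / acc_occ[keep])
  colnames(m) <- c("mean_current", "sd_current", "mean_dwell",
                   paste0("trace_", seq_len(w)))
  rownames(m) <- all_kmers(k)[keep]
  structure(m, n_occurrences = acc_occ[keep],
            class = c("kmer_signal_matrix", "matrix", "array"))
}

#' Principal component projection of a k-mer signal matrix
#'
#' Columns are centered (and optionally scaled); constant columns are
#' dropped with a warning before decomposition. Projections are
#' reproducible up to sign.
#'
#' @param x a numeric matrix (e.g. a [extract_kmer_signals()] result).
#' @param n_components number of components to keep.
#' @param scale. scale columns to unit variance.
#' @return list with `projections` (rows x components), `loadings`,
#'   `explained_variance` (per retained column-space component) and
#'   `explained_variance_ratio`.
#' @export
pca_project <- function(x, n_components = 2, scale. = FALSE) {
  x <- as.matrix(unclass(x))
  if (nrow(x) < n_components + 1)
    stop_invalid("need at least n_components + 1 rows")
  col_var <- apply(x, 2, stats::var)
  if (any(col_var == 0)) {
    warning("dropping ", sum(col_var == 0), " constant column(s)")
    x <- x[, col_var > 0, drop = FALSE]
  }
  p <- prcomp(x, center = TRUE, scale. = scale.)
  var_all <- p$sdev^2
  list(projections = p$x[, seq_len(n_components), drop = FALSE],
       loadings = p$rotation[, seq_len(n_components), drop = FALSE],
       explained_variance = var_all,
       explained_variance_ratio = var_all / sum(var_all))
}
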