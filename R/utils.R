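# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("nanosieve_invalid_argument", "error")))
}

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# DNA string <-> integer codes 0..3 (A,C,G,T)
dna_to_codes <- function(sequence) {
  raw <- charToRaw(toupper(sequence))
  codes <- integer(length(raw))
  codes[] <- NA_integer_
  codes[raw == charToRaw("A")] <- 0L
  codes[raw == charToRaw("C")] <- 1L
  codes[raw == charToRaw("G")] <- 2L
  codes[raw == charToRaw("T")] <- 3L
  codes
}

codes_to_dna <- function(codes) {
  paste(DNA_BASES[codes + 1L], collapse = "")
}

# 1-based lexicographic k-mer index of every window of a code vector
window_kmer_index <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(integer(0))
  nw <- n - k + 1L
  idx <- rep(0, nw)
  for (j in seq_len(k)) {
    idx <- idx * 4 + codes[j:(j + nw - 1L)]
  }
  as.integer(idx + 1L)
}

all_kmers <- function(k) {
  Biostrings::mkAllStrings(DNA_BASES, k)
}

#' Total-variation distance between two discrete distributions
#'
#' @param p,q non-negative vectors of equal length; each is normalized to
#'   sum to 1 before comparison.
#' @return `sum(abs(p - q)) / 2`, a number in `[0, 1]`.
#' @export
tv_distance <- function(p, q) {
  stopifnot(length(p) == length(q))
  p <- p / sum(p)
  q <- q / sum(q)
  sum(abs(p - q)) / 2
}

#' Jensen-Shannon divergence between two discrete distributions
#'
#' @inheritParams tv_distance
#' @return divergence in bits, in `[0, 1]`.
#' @export
js_divergence <- function(p, q) {
  stopifnot(length(p) == length(q))
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    keep <- a > 0
    sum(a[keep] * log2(a[keep] / b[keep]))
  }
  (kl(p, m) + kl(q, m)) / 2
}
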