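# The "sigtab" signal container: a directory holding
#   reads.tsv   read_id, species, class_label, channel, offset_bytes,
#               n_samples, digitisation, range, offset  (fixed column order)
#   signals.bin concatenated little-endian signed 16-bit samples
#   truth.tsv   read_id, base_index, first_sample, last_sample (optional)

SIGTAB_COLS <- c("read_id", "species", "class_label", "channel",
                 "offset_bytes", "n_samples", "digitisation", "range",
                 "offset")

#' Write reads to a sigtab directory
#'
#' @param reads list of `signal_read` objects.
#' @param dir output directory (created if needed).
#' @param truth write the base-to-sample ground-truth table when present.
#' @return `dir`, invisibly.
#' @export
write_sigtab <- function(reads, dir, truth = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_samp <- vapply(reads, function(r) length(r$dac), integer(1))
  offs <- cumsum(c(0, head(n_samp, -1))) * 2L
  tab <- data.frame(
    read_id = vapply(reads, `[[`, character(1), "read_id"),
    species = vapply(reads, `[[`, character(1), "species"),
    class_label = vapply(reads, `[[`, character(1), "class_label"),
    channel = vapply(reads, `[[`, integer(1), "channel"),
    offset_bytes = offs,
    n_samples = n_samp,
    digitisation = vapply(reads, `[[`, numeric(1), "digitisation"),
    range = vapply(reads, `[[`, numeric(1), "range"),
    offset = vapply(reads, `[[`, numeric(1), "offset"),
    stringsAsFactors = FALSE)
  write.table(tab[, SIGTAB_COLS], file.path(dir, "reads.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  con <- file(file.path(dir, "signals.bin"), "wb")
  on.exit(close(con))
  for (r in reads)
    writeBin(as.integer(r$dac), con, size = 2L, endian = "little")
  if (truth && any(vapply(reads, function(r) !is.null(r$base_to_sample),
                          logical(1)))) {
    rows <- lapply(reads, function(r) {
      if (is.null(r$base_to_sample)) return(NULL)
      data.frame(read_id = r$read_id,
                 base_index = r$base_to_sample[, "base_index"],
                 first_sample = r$base_to_sample[, "first_sample"],
                 last_sample = r$base_to_sample[, "last_sample"])
    })
    write.table(do.call(rbind, rows), file.path(dir, "truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a sigtab directory back into signal reads
#'
#' @param dir sigtab directory.
#' @return list of `signal_read` objects (without sequences; with
#'   base-to-sample truth when `truth.tsv` is present).
#' @export
read_sigtab <- function(dir) {
  tab <- read.delim(file.path(dir, "reads.tsv"), stringsAsFactors = FALSE)
  if (!identical(names(tab), SIGTAB_COLS))
    stop_invalid("reads.tsv does not have the expected sigtab columns")
  bin <- file.path(dir, "signals.bin")
  con <- file(bin, "rb")
  on.exit(close(con))
  truth <- NULL
  tf <- file.path(dir, "truth.tsv")
  if (file.exists(tf)) {
    truth <- read.delim(tf, stringsAsFactors = FALSE)
    truth <- split(truth, truth$read_id)
  }
  lapply(seq_len(nrow(tab)), function(i) {
    seek(con, tab$offset_bytes[i])
    dac <- readBin(con, "integer", n = tab$n_samples[i], size = 2L,
                   signed = TRUE, endian = "little")
    bts <- NULL
    if (!is.null(truth) && tab$read_id[i] %in% names(truth)) {
      t <- truth[[tab$read_id[i]]]
      bts <- cbind(base_index = t$base_index,
                   first_sample = t$first_sample,
                   last_sample = t$last_sample)
    }
    structure(list(read_id = tab$read_id[i], species = tab$species[i],
                   class_label = tab$class_label[i], dac = dac,
                   channel = as.integer(tab$channel[i]), sequence = NULL,
                   base_to_sample = bts,
                   digitisation = tab$digitisation[i],
                   offset = tab$offset[i], range = tab$range[i],
                   sample_rate = NA_real_, samples_per_base = NA_real_),
              class = "signal_read")
  })
}

#' Write a reference pool as FASTA
#'
#' @param pool a [reference_pool()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_pool_fasta <- function(pool, path) {
  x <- Biostrings::DNAStringSet(pool$sequences)
  names(x) <- sprintf("%s_%d", pool$name, seq_along(pool$sequences))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a reference pool
#'
#' @param path FASTA path.
#' @param name pool label.
#' @return a [reference_pool()] (with `kmer_bias = NULL`).
#' @export
read_pool_fasta <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  x <- Biostrings::readDNAStringSet(path)
  reference_pool(name, as.character(x))
}
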