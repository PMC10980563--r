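# Fixtures: synthetic inputs and an oracle adaptive-sampling client.
#
# Everything a simulation needs can be generated deterministically so tests
# and experiments run with no downloads: random reference genomes at a
# requested GC, synthetic k-mer pore models in the public table dialect,
# synthetic barcode sets, and a truth-driven "oracle" client that stands in
# for a basecall-and-align adaptive-sampling tool.

#' Generate a synthetic reference FASTA
#'
#' Deterministic random nucleotide contigs at a requested GC content; the
#' same seed always produces byte-identical output.
#'
#' @param path output FASTA path.
#' @param lengths integer vector of contig lengths (one contig each).
#' @param gc target GC fraction.
#' @param seed integer seed.
#' @param names contig names; default `contig_1..n`.
#' @return the path, invisibly.
#' @export
make_reference <- function(path, lengths, gc = 0.5, seed = 1, names = NULL) {
  if (any(lengths <= 0)) stop_config("contig lengths must be positive")
  if (gc < 0 || gc > 1) stop_config("gc must be in [0, 1]")
  if (is.null(names)) names <- paste0("contig_", seq_along(lengths))
  rng <- rng_stream(derive_seed(seed, 77L))
  seqs <- vapply(seq_along(lengths), function(i) {
    u <- rng_runif(rng, lengths[i])
    # split gc mass between G and C, at mass between A and T
    bases <- c("A", "T", "G", "C")
    cut <- c((1 - gc) / 2, 1 - gc, 1 - gc / 2)
    paste(bases[1L + findInterval(u, cut)], collapse = "")
  }, "")
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Generate a synthetic k-mer pore model
#'
#' Stand-in for the published pore-model tables (not obtainable offline):
#' every k-mer over ACGT gets a deterministic pseudo-random z-score level in
#' roughly \[-2.5, 2.5\]. Synthetic by construction — the signal is
#' alignable in shape but carries no real pore physics.
#'
#' @param k k-mer length (e.g. 5 for R9-style, 9 for R10-style).
#' @param seed integer seed.
#' @param level_stdv constant per-k-mer spread.
#' @return a [kmer_model()].
#' @export
make_synthetic_kmer_model <- function(k, seed = 1, level_stdv = 0.1) {
  n <- 4^k
  rng <- rng_stream(derive_seed(seed, 101L + k))
  means <- stats::qnorm(rng_runif(rng, n)) * 1.0
  means <- pmin(pmax(means, -2.5), 2.5)
  bases <- c("A", "C", "G", "T")
  idx <- 0:(n - 1)
  km <- rep("", n)
  for (j in seq_len(k)) {
    km <- paste0(km, bases[(idx %/% 4^(k - j)) %% 4 + 1])
  }
  kmer_model(km, means, level_stdv)
}

#' Generate a synthetic barcode FASTA (12 barcodes, NB-kit style layout)
#'
#' Synthetic stand-ins for a native-barcoding kit: 12 distinct 24-mers named
#' `barcode01..barcode12`.
#'
#' @param path output FASTA path.
#' @param n number of barcodes.
#' @param length barcode length in bases.
#' @param seed integer seed.
#' @return the path, invisibly.
#' @export
make_barcode_fasta <- function(path, n = 12, length = 24, seed = 7) {
  rng <- rng_stream(derive_seed(seed, 303L))
  seqs <- vapply(seq_len(n), function(i) {
    paste(c("A", "C", "G", "T")[1L + as.integer(floor(rng_runif(rng, length) * 4)) %% 4L],
          collapse = "")
  }, "")
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- sprintf("barcode%02d", seq_len(n))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Oracle adaptive-sampling client
#'
#' Decides from simulation truth, not signal: at a read's first chunk it
#' sends `unblock` when the read's origin is outside the target set and
#' `stop_receiving` when it is inside. This isolates the simulator contract
#' from basecaller availability; it refuses to run if the engine does not
#' expose truth, so it cannot be mistaken for a real classifier.
#'
#' @param target_contigs character vector of on-target contig names.
#' @param target_intervals optional data.frame (`contig`, `start`, `end`,
#'   0-based half-open): reads overlapping any interval are on-target.
#' @param unblock_duration seconds a channel stays blocked after an unblock.
#' @return a client object with a `decide(chunks, engine)` function and a
#'   `log()` accessor returning the action log as a data.frame.
#' @export
oracle_client <- function(target_contigs = character(0),
                          target_intervals = NULL, unblock_duration = 0.1) {
  self <- new.env(parent = emptyenv())
  self$decided <- new.env(parent = emptyenv())
  self$rows <- list()
  on_target <- function(tr) {
    if (tr$contig %in% target_contigs) return(TRUE)
    if (!is.null(target_intervals)) {
      hit <- target_intervals$contig == tr$contig &
        target_intervals$start < tr$end & tr$start < target_intervals$end
      if (any(hit)) return(TRUE)
    }
    FALSE
  }
  self$decide <- function(chunks, engine) {
    if (!engine$expose_truth) {
      stop("oracle client requires an engine with expose_truth = TRUE",
           call. = FALSE)
    }
    actions <- list()
    for (ck in chunks) {
      if (!is.null(self$decided[[ck$read_id]])) next
      tr <- engine_read_truth(engine, ck$read_id)
      dec <- if (on_target(tr)) "stop_receiving" else "unblock"
      self$decided[[ck$read_id]] <- dec
      actions[[length(actions) + 1L]] <- list(
        channel = ck$channel, read_number = ck$read_number,
        read_id = ck$read_id, kind = dec,
        unblock_duration = unblock_duration)
      self$rows[[length(self$rows) + 1L]] <- data.frame(
        time_s = engine$now / engine$sample_rate, channel = ck$channel,
        read_id = ck$read_id, decision = dec, stringsAsFactors = FALSE)
    }
    actions
  }
  self$log <- function() {
    if (length(self$rows) == 0L) {
      return(data.frame(time_s = numeric(0), channel = integer(0),
                        read_id = character(0), decision = character(0)))
    }
    do.call(rbind, self$rows)
  }
  class(self) <- "oracle_client"
  self
}

#' Write an oracle client's action log to a TSV
#' @param client an [oracle_client()].
#' @param path output path.
#' @export
write_action_log <- function(client, path) {
  utils::write.table(client$log(), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
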