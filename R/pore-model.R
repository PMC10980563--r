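# Pore model: k-mer level tables and squiggle synthesis.
#
# A nanopore reports an ionic current whose level depends on the k bases
# occupying the pore. Published k-mer models give a z-score-normalized
# expected level per k-mer; synthesis walks the sequence with a sliding
# window, expands each level over its dwell time at the acquisition rate,
# adds Gaussian level noise, denormalizes to picoamps and digitizes to the
# integer DAC counts a sequencer records.

#' Construct a k-mer pore model
#'
#' @param kmers character vector of k-mers over A/C/G/T, all the same length.
#' @param level_mean numeric vector of z-score level means, one per k-mer.
#' @param level_stdv numeric vector of z-score level spreads (all >= 0), or a
#'   single value recycled to every k-mer.
#' @return an object of class `kmer_model` with elements `k`, `kmers`,
#'   `level_mean` and `level_stdv`. Levels are additionally stored in a dense
#'   base-4-indexed table for O(1) lookup during synthesis.
#' @export
kmer_model <- function(kmers, level_mean, level_stdv = 0) {
  if (length(kmers) == 0L) stop("empty k-mer model", call. = FALSE)
  kmers <- toupper(kmers)
  k <- nchar(kmers[1])
  if (any(nchar(kmers) != k)) {
    stop("inconsistent k-mer lengths in model (expected k=", k, ")", call. = FALSE)
  }
  if (any(grepl("[^ACGT]", kmers))) {
    stop("k-mer model contains non-ACGT characters", call. = FALSE)
  }
  if (anyDuplicated(kmers)) stop("duplicate k-mers in model", call. = FALSE)
  level_mean <- as.numeric(level_mean)
  if (length(level_mean) != length(kmers)) {
    stop("level_mean length does not match number of k-mers", call. = FALSE)
  }
  level_stdv <- rep_len(as.numeric(level_stdv), length(kmers))
  if (any(!is.finite(level_mean)) || any(!is.finite(level_stdv))) {
    stop("non-finite level in k-mer model", call. = FALSE)
  }
  if (any(level_stdv < 0)) stop("negative level_stdv in k-mer model", call. = FALSE)

  idx <- kmer_index(kmers, k)
  dense_mean <- rep(NA_real_, 4^k)
  dense_stdv <- rep(NA_real_, 4^k)
  dense_mean[idx + 1L] <- level_mean
  dense_stdv[idx + 1L] <- level_stdv
  structure(
    list(k = k, kmers = kmers, level_mean = level_mean, level_stdv = level_stdv,
         dense_mean = dense_mean, dense_stdv = dense_stdv),
    class = "kmer_model"
  )
}

#' @export
print.kmer_model <- function(x, ...) {
  cat(sprintf("k-mer pore model: k=%d, %d/%d k-mers defined\n",
              x$k, length(x$kmers), 4^x$k))
  invisible(x)
}

# Map A,C,G,T -> 0,1,2,3 for a character string; NA for anything else.
encode_bases <- function(seq) {
  codes <- rep(NA_integer_, 256)
  codes[utf8ToInt("A") + 1L] <- 0L; codes[utf8ToInt("a") + 1L] <- 0L
  codes[utf8ToInt("C") + 1L] <- 1L; codes[utf8ToInt("c") + 1L] <- 1L
  codes[utf8ToInt("G") + 1L] <- 2L; codes[utf8ToInt("g") + 1L] <- 2L
  codes[utf8ToInt("T") + 1L] <- 3L; codes[utf8ToInt("t") + 1L] <- 3L
  codes[utf8ToInt(seq) + 1L]
}

# Base-4 index (0-based) of each k-mer in a vector of k-mer strings.
kmer_index <- function(kmers, k) {
  b <- encode_bases(paste(kmers, collapse = ""))
  dim(b) <- c(k, length(kmers))
  idx <- rep(0, length(kmers))
  for (j in seq_len(k)) idx <- idx * 4 + b[j, ]
  idx
}

# Base-4 index (0-based) of every k-window of a sequence; length n-k+1.
sliding_kmer_index <- function(seq, k) {
  b <- encode_bases(seq)
  if (anyNA(b)) stop("sequence contains non-ACGT characters", call. = FALSE)
  n <- length(b)
  m <- n - k + 1L
  idx <- rep(0, m)
  for (j in seq_len(k)) idx <- idx * 4 + b[j:(j + m - 1L)]
  idx
}

#' Load a k-mer pore-model table
#'
#' Reads the tab-separated dialect used for published pore models:
#' `kmer<TAB>level_mean[<TAB>level_stdv]`, with an optional header line. The
#' k-mer length is inferred from the first data row and every row must agree.
#'
#' @param path path to the tab-separated model table.
#' @param default_stdv level spread to assign when the table has no
#'   level_stdv column (z-score units).
#' @return a [kmer_model()].
#' @export
read_kmer_model <- function(path, default_stdv = 0.15) {
  if (!file.exists(path)) stop_config("k-mer model file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty k-mer model file: ", path, call. = FALSE)
  # a header line is one whose level_mean column is not numeric; a malformed
  # k-mer in a data row must still be reported as such, not skipped
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  has_header <- length(first) >= 2 &&
    is.na(suppressWarnings(as.numeric(first[2])))
  if (has_header) lines <- lines[-1]
  if (length(lines) == 0L) stop("k-mer model file has no data rows: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol < 2L)) stop("k-mer model rows need at least kmer and level_mean", call. = FALSE)
  kmers <- vapply(parts, `[[`, "", 1L)
  means <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(means)) stop("non-numeric level_mean in k-mer model", call. = FALSE)
  if (all(ncol >= 3L)) {
    stdvs <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
    if (anyNA(stdvs)) stop("non-numeric level_stdv in k-mer model", call. = FALSE)
  } else {
    stdvs <- default_stdv
  }
  kmer_model(kmers, means, stdvs)
}

#' Write a k-mer model table (the same dialect `read_kmer_model` reads)
#' @param model a [kmer_model()].
#' @param path output path.
#' @export
write_kmer_model <- function(model, path) {
  utils::write.table(
    data.frame(kmer = model$kmers, level_mean = model$level_mean,
               level_stdv = model$level_stdv),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Signal scaling parameters
#'
#' Linear z-score-to-picoamp denormalization plus the DAC quantization
#' metadata recorded in output files. Defaults are chosen to give signal in a
#' plausible pore-current range; they are configuration, not physics.
#'
#' @param signal_mean mean current in picoamps added during denormalization.
#' @param signal_stdv current spread in picoamps multiplying the z-score.
#' @param digitisation number of integer quantization levels (full scale).
#' @param range full-scale current range in picoamps.
#' @param offset DAC offset in counts.
#' @return an object of class `signal_scaling`.
#' @export
signal_scaling <- function(signal_mean = 90, signal_stdv = 20,
                           digitisation = 8192, range = 1500, offset = 0) {
  if (digitisation <= 0) stop("digitisation must be > 0", call. = FALSE)
  if (range <= 0) stop("range must be > 0", call. = FALSE)
  if (signal_stdv <= 0) stop("signal_stdv must be > 0", call. = FALSE)
  structure(list(signal_mean = signal_mean, signal_stdv = signal_stdv,
                 digitisation = digitisation, range = range, offset = offset),
            class = "signal_scaling")
}

#' Denormalize a z-score level to picoamps
#'
#' The published pore models are z-score normalized; current in picoamps is
#' recovered as `z * signal_stdv + signal_mean`.
#'
#' @param z z-score level(s).
#' @param scaling a [signal_scaling()].
#' @return picoamp value(s), same length as `z`.
#' @export
denormalize <- function(z, scaling) {
  z * scaling$signal_stdv + scaling$signal_mean
}

#' Quantize picoamps to integer DAC counts
#' @param pa picoamp value(s).
#' @param scaling a [signal_scaling()].
#' @return integer DAC counts clamped to `[0, digitisation - 1]`.
#' @export
digitize_pa <- function(pa, scaling) {
  as.integer(pmin(pmax(round(pa * scaling$digitisation / scaling$range - scaling$offset), 0),
                  scaling$digitisation - 1))
}

#' Convert DAC counts back to picoamps
#' @param dac integer DAC counts.
#' @param scaling a [signal_scaling()].
#' @export
undigitize_pa <- function(dac, scaling) {
  (as.numeric(dac) + scaling$offset) * scaling$range / scaling$digitisation
}

#' Dwell model: how long each k-mer level lasts in samples
#'
#' `samples_per_base = sample_rate / bases_per_second` must exceed 1. With
#' `jitter = "none"` dwell is deterministic: cumulative level boundaries are
#' `round(i * samples_per_base)`, so the total length for n levels is exactly
#' `round(n * samples_per_base)`. `jitter = "geometric"` draws each dwell as
#' 1 + Geometric with the same mean, for more realistic dwell spread.
#'
#' @param sample_rate acquisition rate in samples/second (4000 for the
#'   simulated device).
#' @param bases_per_second translocation speed. Nominal defaults by
#'   chemistry: 450 (R9), 400 (R10), 70 (RNA).
#' @param jitter `"none"` or `"geometric"`.
#' @return an object of class `dwell_model`.
#' @export
dwell_model <- function(sample_rate = 4000, bases_per_second = 450,
                        jitter = c("none", "geometric")) {
  jitter <- match.arg(jitter)
  spb <- sample_rate / bases_per_second
  if (!is.finite(spb) || spb <= 1) {
    stop("samples_per_base = sample_rate / bases_per_second must be > 1", call. = FALSE)
  }
  structure(list(sample_rate = sample_rate, bases_per_second = bases_per_second,
                 samples_per_base = spb, jitter = jitter),
            class = "dwell_model")
}

# Cumulative sample boundaries for n levels: c(0, b_1, ..., b_n).
# Deterministic path; jittered path draws from rng.
dwell_boundaries <- function(n, dwell, rng = NULL) {
  if (dwell$jitter == "none" || is.null(rng)) {
    round((0:n) * dwell$samples_per_base)
  } else {
    d <- 1L + rng_rgeom(rng, n, prob = 1 / dwell$samples_per_base)
    cumsum(c(0, d))
  }
}

#' Map a nucleotide sequence to pore-model z-score levels
#'
#' Slides a k-wide window over the sequence; element i is the model level of
#' the k-mer starting at base i (left-aligned window convention), giving
#' `nchar(seq) - k + 1` levels.
#'
#' @param seq a nucleotide string over A/C/G/T.
#' @param model a [kmer_model()].
#' @return numeric vector of z-score levels.
#' @export
sequence_to_levels <- function(seq, model) {
  n <- nchar(seq)
  if (n < model$k) {
    stop("sequence shorter than model k (", model$k, ")", call. = FALSE)
  }
  idx <- sliding_kmer_index(seq, model$k)
  lv <- model$dense_mean[idx + 1L]
  if (anyNA(lv)) stop("sequence contains a k-mer absent from the model", call. = FALSE)
  lv
}

#' Synthesize a raw DAC signal from z-score levels
#'
#' Each level is held for its dwell duration at the acquisition rate;
#' per-sample Gaussian noise (z-score units) is added before denormalization
#' and quantization. With `noise_stdv = 0` and `jitter = "none"` the output
#' is a deterministic function of (levels, dwell, scaling).
#'
#' @param levels numeric vector of z-score levels (non-empty).
#' @param dwell a [dwell_model()].
#' @param scaling a [signal_scaling()].
#' @param noise_stdv per-sample level noise, z-score units, >= 0.
#' @param rng an internal random stream; required when `noise_stdv > 0` or
#'   dwell jitter is enabled.
#' @return integer vector of DAC samples.
#' @export
levels_to_signal <- function(levels, dwell, scaling, noise_stdv = 0, rng = NULL) {
  if (length(levels) == 0L) stop("empty level list", call. = FALSE)
  if (noise_stdv < 0) stop("noise_stdv must be >= 0", call. = FALSE)
  if ((noise_stdv > 0 || dwell$jitter != "none") && is.null(rng)) {
    stop("rng stream required for noisy or jittered synthesis", call. = FALSE)
  }
  bounds <- dwell_boundaries(length(levels), dwell, rng)
  z <- rep.int(levels, diff(bounds))
  if (noise_stdv > 0) z <- z + rng_rnorm(rng, length(z), 0, noise_stdv)
  digitize_pa(denormalize(z, scaling), scaling)
}
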