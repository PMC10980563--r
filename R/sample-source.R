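# Sample source: what molecule enters a pore next.
#
# Draws molecules from a weighted multi-species reference set: species by
# configured weight, contig by length within species (uniform per-base
# coverage), start uniform, length from a Gamma distribution around the
# configured mean, strand 50/50. Amplicon mode instead draws whole
# predefined intervals. Barcoded runs flank the read squiggle with barcode
# arms and adaptor padding.

#' Construct a reference set
#'
#' @param species list of species entries, each a list with `name`, `weight`
#'   (relative proportion, >= 0) and `contigs` (named character vector of
#'   sequences); optionally `barcodes` (names) and `barcode_weights` to
#'   restrict/weight barcode assignment for molecules of that species.
#' @param amplicons optional data.frame with columns `contig`, `start`, `end`
#'   (0-based half-open) and optionally `weight`.
#' @return an object of class `reference_set`.
#' @export
reference_set <- function(species, amplicons = NULL) {
  if (length(species) == 0L) stop_config("reference set has no species")
  w <- vapply(species, function(s) as.numeric(s$weight %||% 1), 0)
  if (any(w < 0) || all(w == 0)) {
    stop_config("species weights must be >= 0 with at least one > 0")
  }
  for (s in species) {
    if (is.null(s$name) || is.null(s$contigs) || length(s$contigs) == 0L) {
      stop_config("each species needs a name and at least one contig")
    }
    if (is.null(names(s$contigs)) || any(!nzchar(names(s$contigs)))) {
      stop_config("contigs must be named")
    }
  }
  obj <- structure(
    list(species = species, weights = w / sum(w), amplicons = NULL),
    class = "reference_set"
  )
  if (!is.null(amplicons)) {
    stopifnot(all(c("contig", "start", "end") %in% names(amplicons)))
    if (is.null(amplicons$weight)) amplicons$weight <- 1
    clen <- contig_lengths(obj)
    for (i in seq_len(nrow(amplicons))) {
      cn <- amplicons$contig[i]
      if (!cn %in% names(clen)) {
        stop_config("amplicon contig '%s' not present in references", cn)
      }
      if (amplicons$start[i] < 0 || amplicons$end[i] <= amplicons$start[i] ||
          amplicons$end[i] > clen[[cn]]) {
        stop_config("amplicon interval %s:%d-%d outside contig bounds",
                    cn, amplicons$start[i], amplicons$end[i])
      }
    }
    obj$amplicons <- amplicons
  }
  obj
}

# Named vector of contig lengths across all species (names must be unique
# across species for amplicon lookup; duplicates take the first).
contig_lengths <- function(refset) {
  out <- integer(0)
  for (s in refset$species) {
    l <- vapply(s$contigs, nchar, 0L)
    out <- c(out, l[!(names(l) %in% names(out))])
  }
  out
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference set: %d species, %d contigs, %s bases%s\n",
              length(x$species),
              sum(vapply(x$species, function(s) length(s$contigs), 0L)),
              format(sum(vapply(x$species, function(s) sum(nchar(s$contigs)), 0)),
                     big.mark = ","),
              if (is.null(x$amplicons)) "" else
                sprintf(", %d amplicons", nrow(x$amplicons))))
  invisible(x)
}

#' Load a reference set from FASTA files (and an optional amplicon BED)
#'
#' @param fasta_paths character vector of FASTA paths, one per species.
#' @param weights relative species proportions (recycled default 1).
#' @param names species names; default the file base names.
#' @param amplicon_bed optional BED path (3+ columns, 0-based half-open).
#' @return a [reference_set()].
#' @export
read_reference_set <- function(fasta_paths, weights = 1, names = NULL,
                               amplicon_bed = NULL) {
  if (length(fasta_paths) == 0L) stop_config("no reference FASTA given")
  for (p in fasta_paths) {
    if (!file.exists(p)) stop_config("reference FASTA not found: %s", p)
  }
  weights <- rep_len(weights, length(fasta_paths))
  if (is.null(names)) {
    names <- tools::file_path_sans_ext(basename(fasta_paths))
  }
  species <- vector("list", length(fasta_paths))
  for (i in seq_along(fasta_paths)) {
    ss <- Biostrings::readDNAStringSet(fasta_paths[i])
    contigs <- as.character(ss)
    names(contigs) <- sub("\\s.*$", "", names(ss))
    species[[i]] <- list(name = names[i], weight = weights[i], contigs = contigs)
  }
  amp <- NULL
  if (!is.null(amplicon_bed)) {
    if (!file.exists(amplicon_bed)) stop_config("amplicon BED not found: %s", amplicon_bed)
    amp <- read_bed3(amplicon_bed)
  }
  reference_set(species, amplicons = amp)
}

# Minimal BED reader: 3+ whitespace-separated columns, 0-based half-open.
read_bed3 <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = paste0("V", 1:3), fill = TRUE,
                          colClasses = c("character", "integer", "integer"))
  if (nrow(df) == 0L) stop_config("empty BED file: %s", path)
  data.frame(contig = df$V1, start = df$V2, end = df$V3,
             stringsAsFactors = FALSE)
}

#' Construct a barcode set
#'
#' @param names barcode names (unique).
#' @param sequences forward barcode sequences (ACGT).
#' @param weights relative barcode proportions, >= 0.
#' @param adaptor_signal_length samples of constant "adaptor" padding added
#'   outside each barcode arm.
#' @param stall_level z-score level of the adaptor padding.
#' @return an object of class `barcode_set`.
#' @export
barcode_set <- function(names, sequences, weights = 1,
                        adaptor_signal_length = 100, stall_level = 1.5) {
  if (length(names) != length(sequences)) {
    stop_config("barcode names and sequences differ in length")
  }
  if (anyDuplicated(names)) stop_config("barcode names must be unique")
  weights <- rep_len(as.numeric(weights), length(names))
  if (any(weights < 0) || (length(weights) && all(weights == 0))) {
    stop_config("barcode weights must be >= 0 with at least one > 0")
  }
  structure(list(names = as.character(names),
                 sequences = toupper(as.character(sequences)),
                 weights = weights / sum(weights),
                 adaptor_signal_length = as.integer(adaptor_signal_length),
                 stall_level = stall_level),
            class = "barcode_set")
}

#' Load barcodes from a FASTA file
#' @param path barcode FASTA.
#' @param weights relative proportions, recycled; default equal.
#' @param ... passed to [barcode_set()].
#' @export
read_barcode_set <- function(path, weights = 1, ...) {
  if (!file.exists(path)) stop_config("barcode FASTA not found: %s", path)
  ss <- Biostrings::readDNAStringSet(path)
  barcode_set(sub("\\s.*$", "", names(ss)), as.character(ss), weights, ...)
}

#' Draw a read length
#'
#' Lengths follow a Gamma distribution with the configured mean (shape 2 by
#' default, giving the right-skewed profile typical of nanopore libraries),
#' clamped below at 200 bases.
#'
#' @param mean_read_length target mean in bases (> 0).
#' @param rng internal random stream.
#' @param shape Gamma shape parameter.
#' @param min_length lower clamp in bases.
#' @return a positive integer length.
#' @export
draw_read_length <- function(mean_read_length, rng, shape = 2, min_length = 200) {
  if (!is.finite(mean_read_length) || mean_read_length <= 0) {
    stop_config("mean_read_length must be > 0")
  }
  l <- rng_rgamma(rng, 1L, shape = shape, rate = shape / mean_read_length)
  max(as.integer(min_length), as.integer(round(l)))
}

# Resolve IUPAC ambiguity codes to concrete bases, one uniform draw per
# ambiguous position, consuming the given stream.
resolve_ambiguity <- function(seq, rng) {
  if (!grepl("[^ACGT]", seq)) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% c("A", "C", "G", "T"))
  u <- rng_runif(rng, length(bad))
  ch[bad] <- c("A", "C", "G", "T")[1L + as.integer(floor(u * 4)) %% 4L]
  paste(ch, collapse = "")
}

#' Draw one molecule from a reference set
#'
#' Species are chosen proportional to weight, contigs proportional to length
#' within the species, the start uniformly on the contig; the drawn length is
#' truncated at the contig end. Minus-strand draws report the forward-strand
#' interval and a reverse-complemented sequence.
#'
#' @param refset a [reference_set()].
#' @param mean_read_length mean read length in bases.
#' @param rng internal random stream.
#' @param shape Gamma shape for the length draw.
#' @param barcodes optional [barcode_set()]; when given, a barcode name is
#'   drawn by weight and recorded on the read.
#' @return a `read_draw` list: read_id, species, contig, start, end, strand,
#'   barcode, sequence (signal is attached later by the engine).
#' @export
draw_read <- function(refset, mean_read_length, rng, shape = 2, barcodes = NULL) {
  si <- if (length(refset$species) == 1L) 1L else
    rng_sample_int(rng, length(refset$species), 1L, prob = refset$weights,
                   replace = TRUE)
  sp <- refset$species[[si]]
  clen <- vapply(sp$contigs, nchar, 0L)
  ci <- if (length(clen) == 1L) 1L else
    rng_sample_int(rng, length(clen), 1L, prob = clen, replace = TRUE)
  L <- draw_read_length(mean_read_length, rng, shape = shape)
  start <- rng_unif_int(rng, clen[ci])
  end <- min(start + L, clen[ci])
  finish_draw(sp, rng, names(clen)[ci],
              substr(sp$contigs[[ci]], start + 1L, end), start, end, barcodes)
}

#' Draw one amplicon molecule
#'
#' One amplicon interval is chosen by weight (uniform by default) and the
#' read spans the whole interval; strand is 50/50.
#'
#' @inheritParams draw_read
#' @export
draw_amplicon <- function(refset, rng, barcodes = NULL) {
  amp <- refset$amplicons
  if (is.null(amp) || nrow(amp) == 0L) stop_config("no amplicons defined")
  ai <- if (nrow(amp) == 1L) 1L else
    rng_sample_int(rng, nrow(amp), 1L, prob = amp$weight, replace = TRUE)
  cn <- amp$contig[ai]
  hit <- NULL
  for (sp in refset$species) {
    if (cn %in% names(sp$contigs)) { hit <- sp; break }
  }
  finish_draw(hit, rng, cn,
              substr(hit$contigs[[cn]], amp$start[ai] + 1L, amp$end[ai]),
              amp$start[ai], amp$end[ai], barcodes)
}

# Complete a draw: strand, ambiguity resolution, barcode assignment. The
# species entry may carry its own barcode names/weights; otherwise the
# run-level barcode set's weights apply.
finish_draw <- function(sp, rng, contig, seq, start, end, barcodes) {
  strand <- if (rng_runif(rng) < 0.5) "+" else "-"
  seq <- resolve_ambiguity(toupper(seq), rng)
  if (strand == "-") seq <- revcomp_chr(seq)
  bc <- NA_character_
  if (!is.null(sp$barcodes) && length(sp$barcodes)) {
    bw <- sp$barcode_weights %||% rep(1, length(sp$barcodes))
    bi <- if (length(sp$barcodes) == 1L) 1L else
      rng_sample_int(rng, length(sp$barcodes), 1L, prob = bw, replace = TRUE)
    bc <- sp$barcodes[bi]
  } else if (!is.null(barcodes)) {
    bi <- if (length(barcodes$names) == 1L) 1L else
      rng_sample_int(rng, length(barcodes$names), 1L, prob = barcodes$weights,
                     replace = TRUE)
    bc <- barcodes$names[bi]
  }
  list(read_id = rng_uuid(rng), species = sp$name, contig = contig,
       start = as.integer(start), end = as.integer(end), strand = strand,
       barcode = bc, sequence = seq, signal = NULL)
}

#' Flank a read squiggle with barcode arms and adaptor padding
#'
#' Output layout: adaptor pad, squiggle of the forward barcode, the read
#' signal, squiggle of the reverse complement of the barcode, adaptor pad.
#' The pad is a constant stretch at the configured stall level.
#'
#' @param read_signal integer DAC vector.
#' @param barcode barcode name present in `bset`.
#' @param bset a [barcode_set()].
#' @param model a [kmer_model()].
#' @param scaling a [signal_scaling()].
#' @param dwell a [dwell_model()].
#' @param noise_stdv z-score noise for the barcode arms.
#' @param rng internal random stream (needed when `noise_stdv > 0`).
#' @return integer DAC vector.
#' @export
flank_with_barcode <- function(read_signal, barcode, bset, model, scaling,
                               dwell, noise_stdv = 0, rng = NULL) {
  bi <- match(barcode, bset$names)
  if (is.na(bi)) stop("unknown barcode name: ", barcode, call. = FALSE)
  fwd <- bset$sequences[bi]
  pad <- rep.int(digitize_pa(denormalize(bset$stall_level, scaling), scaling),
                 bset$adaptor_signal_length)
  arm <- function(s) {
    if (!nzchar(s)) return(integer(0))
    levels_to_signal(sequence_to_levels(s, model), dwell, scaling,
                     noise_stdv = noise_stdv, rng = rng)
  }
  c(pad, arm(fwd), read_signal, arm(revcomp_chr(fwd)), pad)
}
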