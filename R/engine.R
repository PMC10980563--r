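# Run engine: the real-time core of the simulator.
#
# A clocked loop over flow-cell channels. Idle channels draw a new molecule
# (after an exponential inter-read gap), sequencing channels advance a
# translocation cursor at the acquisition rate (4 kHz), finished reads are
# finalized with an end reason and trigger the saturation check, and an
# adaptive-sampling client can unblock (eject) or stop-receiving any read in
# flight. The engine is clock-agnostic: `engine_tick()` takes simulated time,
# so tests and accelerated runs use a virtual clock while `engine_run()` can
# also pace itself against the wall clock.
#
# Signal is materialized lazily: levels are computed when a read starts, but
# noise/dwell expansion to DAC samples happens only for the sample ranges
# actually served or written, from a per-read noise stream. This is
# bit-identical to one-shot synthesis with the same stream and keeps memory
# proportional to what is observed.

#' Create a simulation engine
#'
#' @param refset a [reference_set()].
#' @param model a [kmer_model()].
#' @param health a [health_params()].
#' @param scaling a [signal_scaling()].
#' @param dwell a [dwell_model()].
#' @param n_channels channels to simulate (defaults to
#'   `health$n_starting_channels`).
#' @param seed master seed; every channel derives an independent stream.
#' @param chunk_period seconds of signal per served chunk (cap per call).
#' @param noise_stdv per-sample z-score noise.
#' @param gap_mean mean inter-read gap, simulated seconds.
#' @param unblock_exit_samples extra samples translocated after an unblock.
#' @param mean_read_length mean drawn read length in bases.
#' @param length_shape Gamma shape of the read-length distribution.
#' @param barcodes optional [barcode_set()].
#' @param amplicon_mode draw whole amplicons instead of random fragments.
#' @param keep_signal materialize and keep full signal for output; set FALSE
#'   for yield-only runs (the truth sidecar is still exact).
#' @param expose_truth allow test clients to query read origins.
#' @param run_id,flow_cell_id,sample_id,experiment_id,position_name run
#'   metadata recorded in output.
#' @return an engine object (environment) of class `sim_engine`.
#' @export
engine_new <- function(refset, model, health,
                       scaling = signal_scaling(), dwell = dwell_model(),
                       n_channels = health$n_starting_channels, seed = 1,
                       chunk_period = 1, noise_stdv = 0.15, gap_mean = 0.5,
                       unblock_exit_samples = 0,
                       mean_read_length = health$mean_read_length,
                       length_shape = 2, barcodes = NULL,
                       amplicon_mode = FALSE, keep_signal = TRUE,
                       expose_truth = TRUE, run_id = NULL,
                       flow_cell_id = "FC001", sample_id = "sample_1",
                       experiment_id = "experiment_1",
                       position_name = "SIM-1") {
  e <- new.env(parent = emptyenv())
  e$refset <- refset; e$model <- model; e$health <- health
  e$scaling <- scaling; e$dwell <- dwell
  e$sample_rate <- dwell$sample_rate
  e$n_channels <- as.integer(n_channels)
  e$seed <- seed
  e$chunk_cap <- as.integer(round(chunk_period * dwell$sample_rate))
  e$chunk_period <- chunk_period
  e$noise_stdv <- noise_stdv
  e$gap_mean <- gap_mean
  e$unblock_exit_samples <- as.integer(unblock_exit_samples)
  e$mean_read_length <- mean_read_length
  e$length_shape <- length_shape
  e$barcodes <- barcodes
  e$amplicon_mode <- isTRUE(amplicon_mode)
  e$keep_signal <- isTRUE(keep_signal)
  e$expose_truth <- isTRUE(expose_truth)
  e$master_rng <- rng_stream(derive_seed(seed, 0L))
  e$run_id <- run_id %||% rng_uuid(e$master_rng)
  e$flow_cell_id <- flow_cell_id; e$sample_id <- sample_id
  e$experiment_id <- experiment_id; e$position_name <- position_name
  e$now <- 0
  e$started <- FALSE
  e$finished <- FALSE
  e$start_wall <- NA
  e$finalized <- list()
  e$truth <- new.env(parent = emptyenv())
  e$reads_started <- 0L
  e$reads_finished <- 0L
  e$total_bases <- 0
  e$species_yield <- new.env(parent = emptyenv())
  # Precompute barcode arm levels once; they are read-independent.
  if (!is.null(barcodes)) {
    e$bc_levels <- lapply(seq_along(barcodes$names), function(i) {
      s <- barcodes$sequences[i]
      if (!nzchar(s)) return(list(fwd = numeric(0), rev = numeric(0)))
      list(fwd = sequence_to_levels(s, model),
           rev = sequence_to_levels(revcomp_chr(s), model))
    })
    names(e$bc_levels) <- barcodes$names
    e$pad_dac <- digitize_pa(denormalize(barcodes$stall_level, scaling), scaling)
  }
  class(e) <- "sim_engine"
  e
}

#' @export
print.sim_engine <- function(x, ...) {
  cat(sprintf(
    "nanopore run engine: %d channels @ %g Hz, t=%.1fs, %d reads finalized, %.0f bases\n",
    x$n_channels, x$sample_rate, x$now / x$sample_rate, x$reads_finished,
    x$total_bases))
  invisible(x)
}

#' Start the engine: initialize channel states and RNG streams
#' @param e a `sim_engine`.
#' @export
engine_start <- function(e) {
  if (e$started) stop("engine already started", call. = FALSE)
  init <- init_channels(e$n_channels, e$health, e$master_rng)
  e$channels <- lapply(seq_len(e$n_channels), function(i) {
    ch <- new.env(parent = emptyenv())
    ch$id <- i
    ch$status <- init[[i]]$status
    ch$rng <- rng_stream(derive_seed(e$seed, i))
    ch$next_ready <- 0
    ch$read <- NULL
    ch$read_number <- 0L
    ch$reads_completed <- 0L
    ch$bases_completed <- 0
    ch
  })
  e$started <- TRUE
  e$start_wall <- Sys.time()
  invisible(e)
}

# ---- read lifecycle ---------------------------------------------------------

start_read <- function(e, ch, start_sample) {
  draw <- if (e$amplicon_mode) {
    draw_amplicon(e$refset, ch$rng, barcodes = e$barcodes)
  } else {
    draw_read(e$refset, e$mean_read_length, ch$rng, shape = e$length_shape,
              barcodes = e$barcodes)
  }
  noise_rng <- rng_stream(floor(rng_runif(ch$rng) * 2147483647))
  r <- new.env(parent = emptyenv())
  r$draw <- draw
  r$noise_rng <- noise_rng
  segs <- list()
  add_levels <- function(segs, lv) {
    b <- dwell_boundaries(length(lv), e$dwell,
                          if (e$dwell$jitter == "none") NULL else noise_rng)
    c(segs, list(list(type = "levels", levels = lv, bounds = b,
                      n = b[length(b)])))
  }
  if (!is.null(e$barcodes) && !is.na(draw$barcode)) {
    bl <- e$bc_levels[[draw$barcode]]
    pad_n <- e$barcodes$adaptor_signal_length
    if (pad_n > 0) segs <- c(segs, list(list(type = "pad", n = pad_n)))
    if (length(bl$fwd)) segs <- add_levels(segs, bl$fwd)
    segs <- add_levels(segs, sequence_to_levels(draw$sequence, e$model))
    if (length(bl$rev)) segs <- add_levels(segs, bl$rev)
    if (pad_n > 0) segs <- c(segs, list(list(type = "pad", n = pad_n)))
  } else {
    segs <- add_levels(segs, sequence_to_levels(draw$sequence, e$model))
  }
  ns <- vapply(segs, `[[`, 0, "n")
  r$segments <- segs
  r$seg_offsets <- c(0, cumsum(ns))
  r$total_samples <- as.integer(sum(ns))
  r$buffer <- integer(0)
  r$buf_len <- 0L
  r$served <- 0L
  r$delivered <- 0L
  r$state <- "serving"
  r$read_number <- ch$read_number + 1L
  r$start_sample <- start_sample
  ch$read_number <- r$read_number
  ch$read <- r
  ch$status <- "sequencing"
  e$reads_started <- e$reads_started + 1L
  if (e$expose_truth) {
    e$truth[[draw$read_id]] <- list(
      species = draw$species, contig = draw$contig, start = draw$start,
      end = draw$end, strand = draw$strand, barcode = draw$barcode)
  }
  r
}

# Materialize DAC samples up to sample index `upto` (1-based inclusive).
extend_buffer <- function(e, r, upto) {
  upto <- min(as.integer(upto), r$total_samples)
  if (upto <= r$buf_len) return(invisible(r))
  from <- r$buf_len  # generate samples (from, upto]
  pieces <- list()
  for (si in seq_along(r$segments)) {
    s0 <- r$seg_offsets[si]; s1 <- r$seg_offsets[si + 1L]
    a <- max(from, s0); b <- min(upto, s1)
    if (b <= a) next
    seg <- r$segments[[si]]
    n <- b - a
    if (seg$type == "pad") {
      pieces[[length(pieces) + 1L]] <- rep.int(e$pad_dac, n)
    } else {
      j <- seq.int(a - s0 + 1L, b - s0)  # local sample indices within segment
      lvl_idx <- findInterval(j - 0.5, seg$bounds)
      z <- seg$levels[lvl_idx]
      if (e$noise_stdv > 0) {
        z <- z + rng_rnorm(r$noise_rng, n, 0, e$noise_stdv)
      }
      pieces[[length(pieces) + 1L]] <- digitize_pa(denormalize(z, e$scaling),
                                                   e$scaling)
    }
  }
  r$buffer <- c(r$buffer, unlist(pieces, use.names = FALSE))
  r$buf_len <- upto
  invisible(r)
}

# Bases of the molecule translocated after `samples` of signal: levels whose
# dwell started, counted over sequence segments, plus the k-1 pore overhang,
# capped at the drawn sequence length. Barcode/pad samples do not count
# toward reference bases.
translocated_bases <- function(e, r, samples) {
  nb <- nchar(r$draw$sequence)
  if (samples >= r$total_samples) return(nb)
  # locate the segment holding the read's own levels: it is the one whose
  # level count equals nchar(seq) - k + 1 (unique by construction)
  target_n <- nb - e$model$k + 1L
  covered <- 0L
  for (si in seq_along(r$segments)) {
    seg <- r$segments[[si]]
    if (seg$type != "levels" || length(seg$levels) != target_n) next
    s0 <- r$seg_offsets[si]
    local <- min(max(samples - s0, 0), seg$n)
    if (local <= 0) break
    covered <- findInterval(local - 0.5, seg$bounds)  # dwell started
    if (local > 0 && covered == 0L) covered <- 1L
    break
  }
  if (covered == 0L) return(0L)
  min(nb, covered + e$model$k - 1L)
}

finalize_read <- function(e, ch, reason, translocated_samples, at_sample,
                          extra_delay_samples = 0) {
  r <- ch$read
  translocated_samples <- min(as.integer(translocated_samples), r$total_samples)
  bases <- translocated_bases(e, r, translocated_samples)
  signal <- NULL
  if (e$keep_signal) {
    extend_buffer(e, r, translocated_samples)
    signal <- r$buffer[seq_len(translocated_samples)]
  }
  d <- r$draw
  rec <- list(
    read_id = d$read_id, channel = ch$id, read_number = r$read_number,
    start_sample = r$start_sample, duration_samples = translocated_samples,
    signal = signal, end_reason = reason, barcode = d$barcode,
    species = d$species, contig = d$contig, start = d$start, end = d$end,
    strand = d$strand, drawn_bases = nchar(d$sequence),
    translocated_bases = bases)
  e$finalized[[length(e$finalized) + 1L]] <- rec
  e$reads_finished <- e$reads_finished + 1L
  e$total_bases <- e$total_bases + bases
  sy <- get0(d$species, envir = e$species_yield, ifnotfound = 0)
  assign(d$species, sy + bases, envir = e$species_yield)
  ch$reads_completed <- ch$reads_completed + 1L
  ch$bases_completed <- ch$bases_completed + bases
  ch$read <- NULL
  if (saturate_after_read(e$health, bases, ch$rng)) {
    ch$status <- "saturated"
  } else {
    ch$status <- "idle"
    gap <- rng_rexp(ch$rng, 1L, rate = 1 / e$gap_mean) * e$sample_rate
    ch$next_ready <- at_sample + extra_delay_samples + gap
  }
  invisible(rec)
}

# ---- the clocked loop -------------------------------------------------------

#' Advance the engine to a simulated time
#'
#' Starts reads on free channels (after their inter-read gap), advances the
#' translocation cursor of sequencing channels, and finalizes reads whose
#' signal is exhausted (end reason `signal_positive`), running the
#' saturation check after each. Within one tick a channel may finish a read,
#' wait its gap, and start the next, so large steps lose no throughput.
#'
#' @param e a started `sim_engine`.
#' @param now_s simulated time in seconds (must be non-decreasing).
#' @return invisibly, the engine.
#' @export
engine_tick <- function(e, now_s) {
  stopifnot(e$started)
  now <- floor(now_s * e$sample_rate)
  if (now < e$now) stop("time must be non-decreasing", call. = FALSE)
  e$now <- now
  for (ch in e$channels) {
    repeat {
      if (ch$status == "saturated") break
      if (ch$status == "idle") {
        if (ch$next_ready <= now) {
          start_read(e, ch, ch$next_ready)
        } else break
      } else {
        r <- ch$read
        end_at <- r$start_sample + r$total_samples
        if (end_at <= now) {
          finalize_read(e, ch, "signal_positive", r$total_samples, end_at)
        } else {
          r$served <- as.integer(now - r$start_sample)
          break
        }
      }
    }
  }
  invisible(e)
}

#' Collect pending signal chunks for serving channels
#'
#' Returns, per sequencing channel whose read is still being served, the
#' signal accrued since the previous call, capped at `chunk_period` seconds
#' of samples; the remainder is carried to the next call. Channels whose
#' read was stop-received are omitted.
#'
#' @param e a started `sim_engine`.
#' @param first_channel,last_channel restrict serving to this channel range;
#'   cursors of channels outside the range are left untouched (so several
#'   clients on disjoint ranges each see all of their own channels' signal).
#' @return list of chunks: `channel`, `read_number`, `read_id`, `signal`
#'   (integer DAC), `chunk_start_sample` (offset of the chunk in the read).
#' @export
engine_get_chunks <- function(e, first_channel = 1L,
                              last_channel = e$n_channels) {
  out <- list()
  for (ch in e$channels) {
    if (ch$id < first_channel || ch$id > last_channel) next
    if (ch$status != "sequencing") next
    r <- ch$read
    if (r$state != "serving" || r$served <= r$delivered) next
    n <- min(r$served - r$delivered, e$chunk_cap)
    extend_buffer(e, r, r$delivered + n)
    chunk <- r$buffer[seq.int(r$delivered + 1L, r$delivered + n)]
    out[[length(out) + 1L]] <- list(
      channel = ch$id, read_number = r$read_number, read_id = r$draw$read_id,
      signal = chunk, chunk_start_sample = r$delivered)
    r$delivered <- r$delivered + n
  }
  out
}

#' Apply a client action to a read in flight
#'
#' `unblock` truncates the read at the served cursor (plus the configured
#' exit tail), finalizes it with end reason `unblock_mux_change`, and frees
#' the channel after `unblock_duration` simulated seconds. `stop_receiving`
#' stops streaming further chunks while the molecule sequences to
#' completion.
#'
#' @param e a started `sim_engine`.
#' @param action list with `channel`, `kind` (`"unblock"` or
#'   `"stop_receiving"`), one of `read_number`/`read_id`, and optionally
#'   `unblock_duration` (seconds, default 0.1).
#' @return one of `"success"`, `"failed_read_finished"`,
#'   `"failed_read_stale"`.
#' @export
engine_apply_action <- function(e, action) {
  chn <- action$channel
  if (is.null(chn) || chn < 1 || chn > e$n_channels) {
    stop("action targets unknown channel: ", chn, call. = FALSE)
  }
  kind <- match.arg(action$kind, c("unblock", "stop_receiving"))
  ch <- e$channels[[chn]]
  r <- ch$read
  if (is.null(r)) return("failed_read_finished")
  if (!is.null(action$read_number) && action$read_number != r$read_number) {
    return("failed_read_stale")
  }
  if (!is.null(action$read_id) && action$read_id != r$draw$read_id) {
    return("failed_read_stale")
  }
  if (kind == "stop_receiving") {
    r$state <- "stopped"
    return("success")
  }
  dur <- action$unblock_duration %||% 0.1
  translocated <- min(r$total_samples, r$served + e$unblock_exit_samples)
  finalize_read(e, ch, "unblock_mux_change", translocated, e$now,
                extra_delay_samples = dur * e$sample_rate)
  "success"
}

#' Finalize all in-flight reads at run end
#'
#' Reads still sequencing are truncated at their translocation cursor and
#' recorded with end reason `mux_change`.
#' @param e a started `sim_engine`.
#' @export
engine_finish <- function(e) {
  for (ch in e$channels) {
    if (ch$status == "sequencing") {
      r <- ch$read
      finalize_read(e, ch, "mux_change", r$served, e$now)
    }
  }
  e$finished <- TRUE
  invisible(e)
}

#' Drain finalized reads accumulated since the last drain
#' @param e a `sim_engine`.
#' @return list of read records.
#' @export
engine_drain_finalized <- function(e) {
  out <- e$finalized
  e$finalized <- list()
  out
}

engine_all_saturated <- function(e) {
  all(vapply(e$channels, function(ch) ch$status == "saturated", NA))
}

#' Query a read's true origin (test mode)
#'
#' Only available when the engine was created with `expose_truth = TRUE`;
#' oracle clients use this instead of basecalling.
#' @param e a `sim_engine`.
#' @param read_id read UUID.
#' @export
engine_read_truth <- function(e, read_id) {
  if (!e$expose_truth) {
    stop("truth channel disabled on this engine", call. = FALSE)
  }
  e$truth[[read_id]]
}

#' Run-level counters and metadata
#' @param e a `sim_engine`.
#' @return list with device, acquisition and run description fields.
#' @export
engine_info <- function(e) {
  list(
    position_name = e$position_name,
    n_channels = e$n_channels,
    sample_rate = e$sample_rate,
    run_id = e$run_id,
    flow_cell_id = e$flow_cell_id,
    sample_id = e$sample_id,
    experiment_id = e$experiment_id,
    simulated_seconds = e$now / e$sample_rate,
    reads_started = e$reads_started,
    reads_finished = e$reads_finished,
    yield_bases = e$total_bases,
    species_yield = as.list(e$species_yield)
  )
}

#' Drive the engine over a time window
#'
#' Polls the engine at `poll_period` (simulated seconds): tick, serve chunks
#' to the client, apply the client's actions, and hand finalized reads to
#' the writer. With `realtime = TRUE` simulated time is slaved to the wall
#' clock times `acceleration`; otherwise the loop runs a virtual clock as
#' fast as it can compute.
#'
#' @param e a `sim_engine` (started automatically if not yet).
#' @param duration_s simulated seconds to run.
#' @param client optional client with a `decide(chunks, engine)` function
#'   returning a list of actions (see [oracle_client()]).
#' @param writer optional output writer from [run_writer()].
#' @param poll_period polling interval in simulated seconds (defaults to the
#'   engine chunk period).
#' @param realtime pace against the wall clock.
#' @param acceleration wall-to-simulated time multiplier in realtime mode.
#' @param stop_when optional function(e, writer) returning TRUE to end the
#'   run early.
#' @return the engine, invisibly.
#' @export
engine_run <- function(e, duration_s, client = NULL, writer = NULL,
                       poll_period = e$chunk_period, realtime = FALSE,
                       acceleration = 1, stop_when = NULL) {
  if (!e$started) engine_start(e)
  t0 <- Sys.time()
  t <- e$now / e$sample_rate
  while (t < duration_s) {
    if (realtime) {
      Sys.sleep(poll_period / acceleration)
      t <- min(as.numeric(difftime(Sys.time(), t0, units = "secs")) * acceleration,
               duration_s)
    } else {
      t <- min(t + poll_period, duration_s)
    }
    engine_tick(e, t)
    if (!is.null(client)) {
      chunks <- engine_get_chunks(e)
      for (a in client$decide(chunks, e)) engine_apply_action(e, a)
    }
    if (!is.null(writer)) writer_add(writer, engine_drain_finalized(e))
    if (!is.null(stop_when) && isTRUE(stop_when(e, writer))) break
    if (engine_all_saturated(e)) break
  }
  engine_finish(e)
  if (!is.null(writer)) writer_add(writer, engine_drain_finalized(e))
  invisible(e)
}
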