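# Real-time engine: clock arithmetic, chunk serving, actions, determinism.

test_that("a fully saturated flow cell never produces reads", {
  e <- test_engine(n_channels = 4, initial_saturation = 1,
                   target_yield = 1e6, keep_signal = FALSE)
  engine_start(e)
  for (t in 1:20) engine_tick(e, t)
  expect_equal(e$reads_started, 0)
  expect_length(engine_get_chunks(e), 0)
})

test_that("translocation advances at the acquisition rate", {
  # one busy channel, negligible gaps: 60 s of simulated time moves
  # 60 * 4000 samples through the pore, within one chunk
  e <- test_engine(n_channels = 1, gap_mean = 1e-9, mean_read_length = 5000,
                   keep_signal = FALSE, noise_stdv = 0)
  engine_start(e)
  for (t in seq(1, 60)) engine_tick(e, t)
  done <- sum(vapply(engine_drain_finalized(e), `[[`, 0L, "duration_samples"))
  inflight <- if (!is.null(e$channels[[1]]$read)) e$channels[[1]]$read$served else 0L
  expect_lt(abs((done + inflight) - 240000), 4000 + 1)
})

test_that("chunks respect the cap, the cursor, and stop when time stops", {
  e <- test_engine(n_channels = 1, mean_read_length = 20000, chunk_period = 1)
  engine_start(e)
  engine_tick(e, 1)
  first <- engine_get_chunks(e)
  expect_length(first, 1)
  expect_equal(length(first[[1]]$signal), 4000)
  expect_equal(first[[1]]$chunk_start_sample, 0)
  expect_length(engine_get_chunks(e), 0)  # no elapsed time, no new samples

  # a 0.4 s chunk period caps chunks at 1600 samples
  e2 <- test_engine(n_channels = 1, mean_read_length = 20000, chunk_period = 0.4)
  engine_start(e2)
  engine_tick(e2, 2)
  expect_equal(length(engine_get_chunks(e2)[[1]]$signal), 1600)
})

test_that("served chunks concatenate to a prefix of the stored signal", {
  e <- test_engine(n_channels = 1, mean_read_length = 3000, gap_mean = 10)
  engine_start(e)
  got <- integer(0)
  id <- NULL
  for (t in seq(0.5, 40, by = 0.5)) {
    engine_tick(e, t)
    for (ck in engine_get_chunks(e)) {
      if (is.null(id)) id <- ck$read_id
      if (ck$read_id == id) got <- c(got, ck$signal)
    }
    recs <- engine_drain_finalized(e)
    if (length(recs)) {
      rec <- recs[[1]]
      expect_identical(rec$read_id, id)
      expect_gt(length(got), 0)
      expect_identical(got, rec$signal[seq_along(got)])
      break
    }
  }
})

test_that("engine-materialized signal is bit-identical to one-shot synthesis", {
  e <- test_engine(n_channels = 1, mean_read_length = 3000, gap_mean = 1e6,
                   noise_stdv = 0.15)
  engine_start(e)
  saved <- e$channels[[1]]$rng$state  # clone the channel stream pre-draw
  for (t in 1:60) {
    engine_tick(e, t)
    engine_get_chunks(e)  # force piecewise materialization
    recs <- engine_drain_finalized(e)
    if (length(recs)) break
  }
  rec <- recs[[1]]
  # independent route: replay the channel stream by hand
  rc <- squigglesim:::rng_stream(1)
  rc$state <- saved
  d <- draw_read(e$refset, e$mean_read_length, rc, shape = e$length_shape)
  noise_seed <- floor(squigglesim:::rng_runif(rc) * 2147483647)
  expect_identical(d$read_id, rec$read_id)
  sig <- levels_to_signal(sequence_to_levels(d$sequence, e$model), e$dwell,
                          e$scaling, e$noise_stdv,
                          squigglesim:::rng_stream(noise_seed))
  expect_identical(rec$signal, sig)
  expect_equal(rec$duration_samples, length(sig))
})

test_that("unblock truncates in flight and frees the channel", {
  e <- test_engine(n_channels = 1, mean_read_length = 50000, gap_mean = 0.2)
  engine_start(e)
  engine_tick(e, 1)
  r <- e$channels[[1]]$read
  total <- r$total_samples
  expect_equal(engine_apply_action(e, list(channel = 1, kind = "unblock",
                                           read_number = r$read_number,
                                           unblock_duration = 0.5)),
               "success")
  rec <- engine_drain_finalized(e)[[1]]
  expect_equal(rec$end_reason, "unblock_mux_change")
  expect_equal(rec$duration_samples, 4000)  # served so far + zero exit tail
  expect_lt(rec$duration_samples, total)
  expect_lt(rec$translocated_bases, rec$drawn_bases)
  # channel blocked for unblock_duration then free to restart
  engine_tick(e, 30)
  expect_gte(e$reads_started, 2)
})

test_that("stop_receiving silences chunks but the molecule completes", {
  e <- test_engine(n_channels = 1, mean_read_length = 3000, gap_mean = 1e6)
  engine_start(e)
  engine_tick(e, 1)
  ck <- engine_get_chunks(e)[[1]]
  expect_equal(engine_apply_action(e, list(channel = 1, kind = "stop_receiving",
                                           read_id = ck$read_id)),
               "success")
  engine_tick(e, 2)
  expect_length(engine_get_chunks(e), 0)
  engine_tick(e, 100)
  rec <- engine_drain_finalized(e)[[1]]
  expect_equal(rec$read_id, ck$read_id)
  expect_equal(rec$end_reason, "signal_positive")
  expect_equal(rec$translocated_bases, rec$drawn_bases)
})

test_that("stale and finished actions are acknowledged as failures", {
  e <- test_engine(n_channels = 2, mean_read_length = 3000, gap_mean = 0.1)
  engine_start(e)
  expect_equal(engine_apply_action(e, list(channel = 1, kind = "unblock")),
               "failed_read_finished")  # nothing sequencing yet
  engine_tick(e, 1)
  r <- e$channels[[1]]$read
  expect_equal(engine_apply_action(e, list(channel = 1, kind = "unblock",
                                           read_number = r$read_number - 1L)),
               "failed_read_stale")
  expect_identical(e$channels[[1]]$read$draw$read_id, r$draw$read_id)
  expect_error(engine_apply_action(e, list(channel = 99, kind = "unblock")),
               "unknown channel")
})

test_that("every started read is finalized exactly once with one end reason", {
  e <- test_engine(n_channels = 8, mean_read_length = 2000, seed = 3,
                   target_yield = 3e6, initial_saturation = 0.15,
                   keep_signal = FALSE)
  client <- oracle_client(character(0))  # everything off-target: unblock all
  engine_run(e, 40, client = client)
  recs <- engine_drain_finalized(e)
  expect_equal(e$reads_started, e$reads_finished)
  expect_equal(length(recs), e$reads_finished)
  ids <- vapply(recs, `[[`, "", "read_id")
  expect_false(anyDuplicated(ids) > 0)
  reasons <- vapply(recs, `[[`, "", "end_reason")
  expect_true(all(reasons %in% c("signal_positive", "unblock_mux_change",
                                 "mux_change")))
  # unblocked reads are strictly shorter than drawn whenever truncated early
  ub <- recs[reasons == "unblock_mux_change"]
  expect_gt(length(ub), 0)
  expect_true(all(vapply(ub, `[[`, 0L, "translocated_bases") <
                    vapply(ub, `[[`, 0L, "drawn_bases")))
  # saturated channels stay saturated
  expect_true(all(vapply(e$channels, `[[`, "", "status") != "sequencing"))
})

test_that("fixed seed and scripted actions reproduce identical read sets", {
  scripted <- function() {
    self <- new.env()
    self$decide <- function(chunks, engine) {
      acts <- list()
      for (ck in chunks) {
        if (ck$chunk_start_sample == 0 && ck$channel %% 2 == 1) {
          acts[[length(acts) + 1L]] <- list(channel = ck$channel,
                                            read_number = ck$read_number,
                                            kind = "unblock",
                                            unblock_duration = 0.1)
        } else if (ck$chunk_start_sample == 0) {
          acts[[length(acts) + 1L]] <- list(channel = ck$channel,
                                            read_number = ck$read_number,
                                            kind = "stop_receiving")
        }
      }
      acts
    }
    self
  }
  run_once <- function() {
    e <- test_engine(n_channels = 6, mean_read_length = 3000, seed = 99,
                     target_yield = 5e6, initial_saturation = 0.1,
                     keep_signal = FALSE)
    engine_run(e, 30, client = scripted())
    recs <- engine_drain_finalized(e)
    path <- tempfile(fileext = ".tsv")
    write_truth_sidecar(recs, path)
    path
  }
  p1 <- run_once(); p2 <- run_once()
  expect_identical(readLines(p1), readLines(p2))
  expect_false(length(readLines(p1)) <= 1)
})

test_that("wall-clocked mode serves samples at the nominal rate", {
  e <- test_engine(n_channels = 1, gap_mean = 1e-9, mean_read_length = 5000,
                   keep_signal = FALSE, noise_stdv = 0)
  engine_start(e)
  engine_run(e, 10, realtime = TRUE, acceleration = 200, poll_period = 0.5)
  total <- sum(vapply(engine_drain_finalized(e), `[[`, 0L, "duration_samples"))
  expect_lt(abs(total - 40000) / 40000, 0.05)
})
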