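# Control API: live-reads message contract, metadata endpoints, transport.

test_that("setup is mandatory and channel ranges filter chunk delivery", {
  e <- test_engine(n_channels = 4, mean_read_length = 20000)
  engine_start(e)
  s <- api_session(e)
  resp <- api_handle(s, list(type = "get_chunks"))
  expect_equal(resp$type, "error")
  expect_match(resp$message, "setup")

  expect_equal(api_handle(s, list(type = "setup", first_channel = 1,
                                  last_channel = 2))$type, "setup_ack")
  bad <- api_handle(api_session(e), list(type = "setup", first_channel = 1,
                                         last_channel = 99))
  expect_equal(bad$type, "error")

  engine_tick(e, 1)
  # two clients on disjoint ranges see only their own channels
  s2 <- api_session(e)
  api_handle(s2, list(type = "setup", first_channel = 3, last_channel = 4))
  d1 <- api_handle(s, list(type = "get_chunks"))
  d2 <- api_handle(s2, list(type = "get_chunks"))
  expect_true(all(vapply(d1$chunks, `[[`, 0, "channel") <= 2))
  expect_true(all(vapply(d2$chunks, `[[`, 0, "channel") >= 3))
  expect_equal(length(d1$chunks) + length(d2$chunks), 4)
  expect_true(all(vapply(d1$chunks, `[[`, "", "chunk_classification") == "strand"))
})

test_that("actions route through the engine with per-action acknowledgements", {
  e <- test_engine(n_channels = 2, mean_read_length = 20000)
  engine_start(e)
  s <- api_session(e)
  api_handle(s, list(type = "setup", first_channel = 1, last_channel = 2))
  engine_tick(e, 1)
  d <- api_handle(s, list(type = "get_chunks"))
  acts <- lapply(seq_along(d$chunks), function(i) {
    ck <- d$chunks[[i]]
    list(action_id = paste0("a", i), channel = ck$channel,
         read_number = ck$read_number, kind = "unblock",
         unblock_duration = 0.1)
  })
  acts[[length(acts) + 1L]] <- list(action_id = "oor", channel = 77,
                                    kind = "unblock")
  r <- api_handle(s, list(type = "actions", actions = acts))
  expect_equal(r$type, "action_responses")
  expect_equal(r$n_success, 2)
  expect_equal(r$responses[[3]]$outcome, "failed_channel_out_of_range")
  recs <- engine_drain_finalized(e)
  expect_true(all(vapply(recs, `[[`, "", "end_reason") == "unblock_mux_change"))
})

test_that("metadata endpoints report device, acquisition and run facts", {
  e <- test_engine(n_channels = 512, mean_read_length = 1000,
                   keep_signal = FALSE, seed = 8)
  engine_start(e)
  fc <- api_metadata(e, "device.get_flow_cell_info")
  expect_equal(fc$sample_rate, 4000)
  expect_equal(fc$channel_count, 512)
  pos <- api_metadata(e, "manager.flow_cell_positions",
                      server = list(data_port = 9001))
  expect_equal(pos$positions[[1]]$rpc_port, 9001)
  expect_equal(api_metadata(e, "instance.get_version_info")$product, "squigglesim")
  expect_equal(api_metadata(e, "acquisition.get_acquisition_info")$yield_bases, 0)
  expect_match(api_metadata(e, "what.is_this")$message, "unimplemented")

  # acquisition yield is exact bookkeeping over finished reads
  engine_run(e, 20)
  recs <- engine_drain_finalized(e)
  acq <- api_metadata(e, "acquisition.get_acquisition_info")
  expect_equal(acq$yield_bases, sum(vapply(recs, `[[`, 0L, "translocated_bases")))
  expect_equal(acq$reads_finished, length(recs))
})

test_that("API-driven adaptive sampling equals direct engine actions", {
  run_direct <- function() {
    e <- test_engine(n_channels = 4, mean_read_length = 5000, seed = 31,
                     keep_signal = FALSE, gap_mean = 0.3)
    engine_run(e, 25, client = oracle_client(character(0)))
    engine_drain_finalized(e)
  }
  run_api <- function() {
    e <- test_engine(n_channels = 4, mean_read_length = 5000, seed = 31,
                     keep_signal = FALSE, gap_mean = 0.3)
    engine_start(e)
    s <- api_session(e)
    api_handle(s, list(type = "setup", first_channel = 1, last_channel = 4))
    decided <- new.env()
    t <- 0
    while (t < 25) {
      t <- min(t + 1, 25)
      engine_tick(e, t)
      d <- api_handle(s, list(type = "get_chunks"))
      acts <- list()
      for (ck in d$chunks) {
        if (!is.null(decided[[ck$read_id]])) next
        decided[[ck$read_id]] <- TRUE  # off-target everywhere: unblock
        acts[[length(acts) + 1L]] <- list(channel = ck$channel,
                                          read_number = ck$read_number,
                                          kind = "unblock",
                                          unblock_duration = 0.1)
      }
      if (length(acts)) api_handle(s, list(type = "actions", actions = acts))
    }
    engine_finish(e)
    engine_drain_finalized(e)
  }
  a <- run_direct(); b <- run_api()
  expect_equal(length(a), length(b))
  strip <- function(recs) lapply(recs, function(r) r[setdiff(names(r), "signal")])
  expect_identical(strip(a), strip(b))
})

test_that("the JSON-over-TCP transport carries the same contract", {
  e <- test_engine(n_channels = 2, mean_read_length = 20000)
  engine_start(e)
  engine_tick(e, 1)
  port <- 30011 + (Sys.getpid() %% 500)
  sock <- serverSocket(port)
  on.exit(close(sock), add = TRUE)
  client <- socketConnection("localhost", port, blocking = TRUE, open = "r+")
  on.exit(close(client), add = TRUE)
  server_con <- socketAccept(sock, blocking = TRUE, open = "r+")
  on.exit(close(server_con), add = TRUE)

  ask <- function(msg) {
    writeLines(as.character(squigglesim:::api_encode(msg)), client)
    flush(client)
    api_serve_connection(e, server_con, n_messages = 1)
    squigglesim:::api_decode(readLines(client, n = 1))
  }
  expect_equal(ask(list(type = "metadata",
                        endpoint = "device.get_flow_cell_info"))$sample_rate, 4000)
  # NB: api_serve_connection opens a fresh session per call here, so the
  # protocol guard is what a pre-setup poll exercises
  bad <- ask(list(type = "get_chunks"))
  expect_equal(bad$type, "error")
})

test_that("an absent client never stalls sequencing", {
  e <- test_engine(n_channels = 2, mean_read_length = 1000, keep_signal = FALSE)
  engine_run(e, 15)  # no client attached at all
  expect_gt(e$reads_finished, 0)
})
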