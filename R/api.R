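# Control API: the sequencer-control surface adaptive-sampling clients use.
#
# Mirrors the message semantics of the MinKNOW-style live-reads service: a
# client first sends a setup message (channel range, data type), then polls
# for chunk batches and streams back unblock / stop_receiving actions, each
# of which is acknowledged. Metadata endpoints describe the position, the
# flow cell, the acquisition and the run. The original service is gRPC; no
# gRPC stack exists in this R environment, so the same contract is exposed
# at message level (R lists) with an optional line-delimited JSON-over-TCP
# transport for out-of-process clients.

#' Open a live-reads API session on an engine
#'
#' @param engine a started `sim_engine`.
#' @return a session object; pass messages to [api_handle()].
#' @export
api_session <- function(engine) {
  s <- new.env(parent = emptyenv())
  s$engine <- engine
  s$setup <- NULL
  class(s) <- "api_session"
  s
}

api_error <- function(msg) list(type = "error", message = msg)

#' Handle one live-reads API message
#'
#' Message types, mirroring the live-reads protocol:
#' \describe{
#'   \item{setup}{`first_channel`, `last_channel` (1-based inclusive range),
#'     optional `raw_data_type`. Must precede everything else.}
#'   \item{get_chunks}{returns `type="data"` with the pending chunk batch,
#'     filtered to the setup channel range.}
#'   \item{actions}{`actions` = list of `{action_id, channel, read_number
#'     or read_id, kind, unblock_duration}`; returns per-action outcomes.}
#' }
#'
#' @param session an [api_session()].
#' @param msg message list with a `type` field.
#' @return response list; `type="error"` for protocol violations.
#' @export
api_handle <- function(session, msg) {
  e <- session$engine
  type <- msg$type %||% ""
  if (type == "setup") {
    first <- msg$first_channel %||% 1L
    last <- msg$last_channel %||% e$n_channels
    if (first < 1 || last > e$n_channels || first > last) {
      return(api_error(sprintf("channel range %d-%d outside 1-%d",
                               first, last, e$n_channels)))
    }
    session$setup <- list(first_channel = as.integer(first),
                          last_channel = as.integer(last),
                          raw_data_type = msg$raw_data_type %||% "uncalibrated")
    return(list(type = "setup_ack", first_channel = session$setup$first_channel,
                last_channel = session$setup$last_channel))
  }
  if (is.null(session$setup)) {
    return(api_error("protocol error: setup message required before anything else"))
  }
  if (type == "get_chunks") {
    chunks <- engine_get_chunks(e, session$setup$first_channel,
                                session$setup$last_channel)
    return(list(type = "data",
                chunks = lapply(chunks, function(ck) {
                  list(channel = ck$channel, read_number = ck$read_number,
                       read_id = ck$read_id,
                       chunk_start_sample = ck$chunk_start_sample,
                       chunk_classification = "strand",
                       signal = ck$signal)
                })))
  }
  if (type == "actions") {
    responses <- lapply(msg$actions, function(a) {
      if (is.null(a$channel) || a$channel < session$setup$first_channel ||
          a$channel > session$setup$last_channel) {
        return(list(action_id = a$action_id %||% NA,
                    outcome = "failed_channel_out_of_range"))
      }
      out <- engine_apply_action(e, a)
      list(action_id = a$action_id %||% NA, outcome = out)
    })
    ok <- sum(vapply(responses, function(r) r$outcome == "success", NA))
    return(list(type = "action_responses", responses = responses,
                n_success = ok, n_failed = length(responses) - ok))
  }
  api_error(paste0("unknown message type: ", type))
}

#' Query a metadata endpoint
#'
#' The endpoint subset an adaptive-sampling client needs: position listing,
#' flow-cell/device description, acquisition counters, run info and version.
#' Anything else returns an "unimplemented" error, like a stub server.
#'
#' @param engine a `sim_engine`.
#' @param endpoint endpoint name, e.g. `"manager.flow_cell_positions"`,
#'   `"device.get_flow_cell_info"`, `"acquisition.get_acquisition_info"`,
#'   `"protocol.get_run_info"`, `"instance.get_version_info"`.
#' @param server optional server config (ports reported in the position
#'   listing).
#' @return response list.
#' @export
api_metadata <- function(engine, endpoint, server = NULL) {
  info <- engine_info(engine)
  switch(
    endpoint,
    "manager.flow_cell_positions" = list(
      positions = list(list(name = info$position_name,
                            state = "running",
                            rpc_port = server$data_port %||% NA_integer_))),
    "device.get_flow_cell_info" = list(
      channel_count = info$n_channels,
      sample_rate = info$sample_rate,
      flow_cell_id = info$flow_cell_id,
      product_code = "SIM-MIN"),
    "acquisition.get_acquisition_info" = list(
      run_id = info$run_id,
      state = if (engine$finished) "finished" else "running",
      yield_bases = info$yield_bases,
      reads_started = info$reads_started,
      reads_finished = info$reads_finished,
      simulated_seconds = info$simulated_seconds),
    "protocol.get_run_info" = list(
      run_id = info$run_id,
      experiment_id = info$experiment_id,
      sample_id = info$sample_id,
      flow_cell_id = info$flow_cell_id),
    "instance.get_version_info" = list(
      version = as.character(utils::packageVersion("squigglesim")),
      product = "squigglesim"),
    api_error(paste0("unimplemented endpoint: ", endpoint))
  )
}

# ---- JSON-over-TCP transport ------------------------------------------------

api_encode <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}

api_decode <- function(line) {
  jsonlite::fromJSON(line, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                     simplifyMatrix = FALSE)
}

#' Serve the API over an open connection (one JSON message per line)
#'
#' Processes messages until `n_messages` have been handled, the peer closes,
#' or a `{"type":"close"}` message arrives. Live-reads messages are routed
#' through [api_handle()]; `{"type":"metadata","endpoint":...}` through
#' [api_metadata()].
#'
#' @param engine a started `sim_engine`.
#' @param con a connection open for text read/write.
#' @param server optional server config for metadata responses.
#' @param n_messages maximum number of messages to process.
#' @return number of messages handled, invisibly.
#' @export
api_serve_connection <- function(engine, con, server = NULL,
                                 n_messages = Inf) {
  session <- api_session(engine)
  handled <- 0
  while (handled < n_messages) {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) break
    msg <- tryCatch(api_decode(line), error = function(e) NULL)
    resp <- if (is.null(msg)) {
      api_error("malformed JSON message")
    } else if (identical(msg$type, "close")) {
      writeLines(as.character(api_encode(list(type = "bye"))), con)
      flush(con)
      break
    } else if (identical(msg$type, "metadata")) {
      api_metadata(engine, msg$endpoint %||% "", server = server)
    } else {
      api_handle(session, msg)
    }
    writeLines(as.character(api_encode(resp)), con)
    flush(con)
    handled <- handled + 1
  }
  invisible(handled)
}

#' Serve the API on a TCP port (blocking)
#'
#' Accepts one client at a time and serves it with
#' [api_serve_connection()]. Intended for out-of-process clients; tests use
#' the in-process message surface instead.
#'
#' @param engine a started `sim_engine`.
#' @param port TCP port.
#' @param server optional server config.
#' @param max_clients accept at most this many sequential clients.
#' @export
api_serve_tcp <- function(engine, port, server = NULL, max_clients = 1L) {
  sock <- serverSocket(port)
  on.exit(close(sock), add = TRUE)
  for (i in seq_len(max_clients)) {
    con <- socketAccept(sock, blocking = TRUE, open = "r+")
    api_serve_connection(engine, con, server = server)
    close(con)
  }
  invisible(NULL)
}
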