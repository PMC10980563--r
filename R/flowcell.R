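# Flow-cell health: channel saturation across a run.
#
# Real flow cells lose active pores over a run. Two mechanisms are modelled:
# a fraction of channels is saturated from the start (default 15%), and
# after every read a channel saturates with probability
#   base_chance * read_length / 10000,
# where base_chance = mean_read_length * n_starting_channels / target_yield.
# Saturation is absorbing. The length scaling captures that long molecules
# block pores more often; with ~10 kb reads the expected total yield is close
# to the configured target.

#' Flow-cell health parameters
#'
#' @param target_yield intended run yield in bases (> 0).
#' @param mean_read_length mean read length in bases (> 0).
#' @param n_starting_channels number of channels on the flow cell (>= 1).
#' @param initial_saturation_fraction probability a channel is saturated at
#'   run start (default 0.15).
#' @return an object of class `health_params`.
#' @export
health_params <- function(target_yield, mean_read_length, n_starting_channels,
                          initial_saturation_fraction = 0.15) {
  if (!is.finite(target_yield) || target_yield <= 0) {
    stop_config("target_yield must be > 0")
  }
  if (!is.finite(mean_read_length) || mean_read_length <= 0) {
    stop_config("mean_read_length must be > 0")
  }
  if (n_starting_channels < 1) stop_config("n_starting_channels must be >= 1")
  if (initial_saturation_fraction < 0 || initial_saturation_fraction > 1) {
    stop_config("initial_saturation_fraction must be in [0, 1]")
  }
  structure(list(target_yield = target_yield,
                 mean_read_length = mean_read_length,
                 n_starting_channels = as.integer(n_starting_channels),
                 initial_saturation_fraction = initial_saturation_fraction),
            class = "health_params")
}

#' Per-read base saturation chance
#'
#' `mean_read_length * n_starting_channels / target_yield`, clamped to at
#' most 1. This is the probability scale such that a channel is expected to
#' deliver about `target_yield / n_starting_channels` bases before dying
#' (once multiplied by read length / 10000 per read).
#'
#' @param params a [health_params()].
#' @return a probability in (0, 1].
#' @export
base_chance <- function(params) {
  min(1, params$mean_read_length * params$n_starting_channels / params$target_yield)
}

#' Initialize channel states
#'
#' Each channel is independently saturated with
#' `initial_saturation_fraction`; the rest start idle.
#'
#' @param n number of channels (>= 1).
#' @param params a [health_params()].
#' @param rng internal random stream.
#' @return list of channel states: `channel`, `status`
#'   (`"idle"`/`"saturated"`), `reads_completed`, `bases_completed`.
#' @export
init_channels <- function(n, params, rng) {
  if (n < 1) stop_config("need at least one channel")
  sat <- rng_runif(rng, n) < params$initial_saturation_fraction
  lapply(seq_len(n), function(i) {
    list(channel = i, status = if (sat[i]) "saturated" else "idle",
         reads_completed = 0L, bases_completed = 0)
  })
}

#' Decide whether a channel saturates after a read
#'
#' True with probability `min(1, base_chance(params) * read_length / 10000)`.
#' Exactly one random variate is consumed per decision regardless of the
#' outcome, so channel streams stay aligned across runs.
#'
#' @param params a [health_params()].
#' @param read_length bases actually translocated by the finished read.
#' @param rng internal random stream.
#' @return logical.
#' @export
saturate_after_read <- function(params, read_length, rng) {
  if (read_length < 0) stop_config("read_length must be >= 0")
  p <- min(1, base_chance(params) * read_length / 10000)
  rng_runif(rng) < p
}

#' Simulate total yield of a flow cell to exhaustion
#'
#' Draws reads channel by channel until every channel saturates, using the
#' configured read-length distribution, and returns the total bases. This is
#' the module-level calibration check: with 10 kb mean reads and no initial
#' saturation the expectation is close to `target_yield`.
#'
#' @param params a [health_params()].
#' @param rng internal random stream.
#' @param shape Gamma shape of the read-length distribution.
#' @param max_reads_per_channel safety cap.
#' @return total yield in bases (numeric scalar).
#' @export
simulate_channel_yield <- function(params, rng, shape = 2,
                                   max_reads_per_channel = 100000L) {
  channels <- init_channels(params$n_starting_channels, params, rng)
  total <- 0
  for (ch in channels) {
    if (ch$status == "saturated") next
    for (i in seq_len(max_reads_per_channel)) {
      L <- draw_read_length(params$mean_read_length, rng, shape = shape)
      total <- total + L
      if (saturate_after_read(params, L, rng)) break
    }
  }
  total
}
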