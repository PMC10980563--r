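# Top-level orchestration: configuration -> engine -> output, plus the
# paired control/adaptive enrichment experiment.

build_engine <- function(cfg, seed = NULL, keep_signal = NULL,
                         expose_truth = TRUE) {
  p <- cfg$profile
  srv <- cfg$server
  model <- if (!is.null(p$pore_model)) {
    read_kmer_model(p$pore_model)
  } else {
    make_synthetic_kmer_model(5, seed = 1)
  }
  check_chemistry(p, model)
  refs <- vapply(p$sample, `[[`, "", "reference")
  wts <- vapply(p$sample, `[[`, 0, "weight")
  nms <- vapply(p$sample, `[[`, "", "name")
  refset <- read_reference_set(refs, weights = wts, names = nms)
  amp_all <- NULL
  for (i in seq_along(p$sample)) {
    s <- p$sample[[i]]
    refset$species[[i]]$barcodes <- s$barcodes
    refset$species[[i]]$barcode_weights <- s$barcode_weights
    if (!is.null(s$amplicons)) {
      amp_all <- rbind(amp_all, read_bed3(s$amplicons))
    }
  }
  if (!is.null(amp_all)) {
    refset <- reference_set(refset$species, amplicons = amp_all)
  }
  barcodes <- NULL
  if (any(vapply(p$sample, function(s) length(s$barcodes) > 0, NA))) {
    wanted <- unique(unlist(lapply(p$sample, `[[`, "barcodes")))
    bset <- read_barcode_set(p$barcode_fasta,
                             adaptor_signal_length = p$adaptor_signal_length,
                             stall_level = p$stall_level)
    missing <- setdiff(wanted, bset$names)
    if (length(missing)) {
      stop_config("barcodes not in FASTA: %s", paste(missing, collapse = ", "))
    }
    barcodes <- bset
  }
  health <- health_params(
    target_yield = p$target_yield,
    mean_read_length = p$mean_read_length,
    n_starting_channels = srv$n_channels,
    initial_saturation_fraction = p$initial_saturation_fraction)
  dwell <- dwell_model(sample_rate = srv$sample_rate,
                       bases_per_second = p$bases_per_second,
                       jitter = p$jitter)
  engine_new(
    refset = refset, model = model, health = health,
    scaling = signal_scaling(), dwell = dwell,
    n_channels = srv$n_channels, seed = seed %||% p$seed,
    chunk_period = p$chunk_period, noise_stdv = p$noise_stdv,
    gap_mean = p$gap_mean, unblock_exit_samples = p$unblock_exit_samples,
    mean_read_length = p$mean_read_length, length_shape = p$length_shape,
    barcodes = barcodes, amplicon_mode = p$amplicon_mode,
    keep_signal = keep_signal %||% (p$output_format == "fast5"),
    expose_truth = expose_truth,
    sample_id = p$sample_id, experiment_id = p$experiment_id,
    flow_cell_id = p$flow_cell_id, position_name = srv$position_name)
}

#' Run a configured simulation end to end
#'
#' Loads the INI + TOML configuration, builds the engine, runs it for the
#' requested simulated duration (virtual clock unless `realtime`), streams
#' finalized reads through a batching writer, and records the resolved
#' profile alongside the output for provenance.
#'
#' @param ini_path server INI path.
#' @param profile_path simulation-profile TOML path.
#' @param duration_s simulated seconds to run.
#' @param out_dir output root directory.
#' @param client optional adaptive-sampling client (see [oracle_client()]).
#' @param seed optional master-seed override.
#' @param format optional output-format override (`"fast5"`/`"none"`).
#' @param realtime pace against the wall clock at the profile's
#'   `acceleration`.
#' @param stop_when optional early-stop predicate `function(engine, writer)`.
#' @return list: engine `info`, writer `output` (paths), and the `client`.
#' @export
simulate_run <- function(ini_path, profile_path, duration_s, out_dir,
                         client = NULL, seed = NULL, format = NULL,
                         realtime = FALSE, stop_when = NULL) {
  cfg <- load_profile(ini_path, profile_path)
  if (!is.null(format)) cfg$profile$output_format <- format
  e <- build_engine(cfg, seed = seed,
                    keep_signal = cfg$profile$output_format == "fast5")
  engine_start(e)
  w <- run_writer(out_dir, writer_meta(e),
                  format = cfg$profile$output_format,
                  batch_size = cfg$profile$batch_size)
  write_profile(cfg$profile, file.path(w$run_dir, "resolved_profile.toml"))
  engine_run(e, duration_s, client = client, writer = w,
             realtime = realtime, acceleration = cfg$profile$acceleration,
             stop_when = stop_when)
  out <- writer_finalize(w)
  list(info = engine_info(e), output = out, client = client)
}

#' Paired control / adaptive-sampling enrichment experiment
#'
#' Builds a synthetic genome in which a configurable fraction of the
#' sequence is designated on-target, then runs two simulations from
#' identical seeds: a control (no client) and an adaptive run in which the
#' oracle client unblocks every off-target read at its first chunk. Yields
#' are recomputed from the truth sidecars. Enrichment is the ratio of
#' on-target bases between the two runs.
#'
#' @param seed master seed for both runs.
#' @param out_dir output directory (two run trees are created).
#' @param duration_s simulated seconds per run.
#' @param n_channels flow-cell channels.
#' @param mean_read_length mean drawn read length, bases.
#' @param genome_bases total synthetic genome size.
#' @param on_target_fraction fraction of the genome that is on-target.
#' @param target_yield flow-cell health target yield, bases.
#' @param chunk_period decision chunk length, seconds.
#' @return list with per-run yields, the on-target fold change, and median
#'   read lengths by category.
#' @export
run_enrichment_experiment <- function(seed, out_dir,
                                      duration_s = 120,
                                      n_channels = 512,
                                      mean_read_length = 28000,
                                      genome_bases = 5e6,
                                      on_target_fraction = 0.04,
                                      target_yield = 5e8,
                                      chunk_period = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ref <- file.path(out_dir, "synthetic_genome.fasta")
  on_len <- round(genome_bases * on_target_fraction)
  make_reference(ref, lengths = c(on_len, genome_bases - on_len),
                 gc = 0.5, seed = seed,
                 names = c("target_region", "background"))
  model_path <- file.path(out_dir, "synthetic_r9_model.tsv")
  write_kmer_model(make_synthetic_kmer_model(5, seed = 1), model_path)
  ini <- file.path(out_dir, "server.ini")
  writeLines(c("[server]",
               "manager_port = 10001",
               "data_port = 10002",
               "position_name = SIM-1",
               "[device]",
               sprintf("n_channels = %d", n_channels),
               "sample_rate = 4000"), ini)
  profile <- file.path(out_dir, "profile.toml")
  writeLines(c(sprintf("target_yield = %.0f", target_yield),
               sprintf("mean_read_length = %.0f", mean_read_length),
               "initial_saturation_fraction = 0.15",
               sprintf('pore_model = "%s"', model_path),
               'chemistry = "R9"',
               sprintf("chunk_period = %s", format(chunk_period)),
               'output_format = "none"',
               sprintf("seed = %d", seed),
               "[[sample]]",
               'name = "synthetic"',
               sprintf('reference = "%s"', ref),
               "weight = 1"), profile)

  run_one <- function(label, client) {
    res <- simulate_run(ini, profile, duration_s,
                        file.path(out_dir, label), client = client,
                        seed = seed)
    read_truth_sidecar(res$output$sidecar)
  }
  control <- run_one("control", NULL)
  adaptive <- run_one("adaptive", oracle_client("target_region"))

  summarize <- function(df) {
    on <- df$contig == "target_region"
    ended <- df$end_reason != "mux_change"  # exclude run-end truncation
    list(on_target_bases = sum(df$translocated_bases[on]),
         off_target_bases = sum(df$translocated_bases[!on]),
         total_bases = sum(df$translocated_bases),
         n_reads = nrow(df),
         median_on = stats::median(df$translocated_bases[on & ended]),
         median_off = stats::median(df$translocated_bases[!on & ended]))
  }
  cs <- summarize(control)
  as <- summarize(adaptive)
  list(control = cs, adaptive = as,
       fold_change = as$on_target_bases / cs$on_target_bases,
       median_on_ratio = as$median_on / cs$median_on,
       median_off_ratio = as$median_off / cs$median_off)
}
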