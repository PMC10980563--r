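# Shared in-code fixtures: every object is built fresh and deterministically;
# nothing is downloaded or stored.

test_model <- function(k = 5, seed = 1) make_synthetic_kmer_model(k, seed = seed)

test_scaling <- function() signal_scaling()

test_dwell <- function(bases_per_second = 450) {
  dwell_model(sample_rate = 4000, bases_per_second = bases_per_second)
}

# Random ACGT string from a dedicated stream.
random_seq <- function(n, seed = 1) {
  rng <- squigglesim:::rng_stream(seed)
  paste(c("A", "C", "G", "T")[1L + as.integer(floor(
    squigglesim:::rng_runif(rng, n) * 4)) %% 4L], collapse = "")
}

# Single-species in-memory reference set.
test_refset <- function(contigs, name = "sp1", weight = 1) {
  reference_set(list(list(name = name, weight = weight, contigs = contigs)))
}

# A small ready-to-run engine over a synthetic genome. Saturation off and
# huge target yield by default so tests control channel lifecycles.
test_engine <- function(n_channels = 2, seed = 42, contig_len = 200000,
                        mean_read_length = 2000, noise_stdv = 0.15,
                        initial_saturation = 0, target_yield = 1e12,
                        gap_mean = 0.5, keep_signal = TRUE, ...) {
  ref <- test_refset(c(chrA = random_seq(contig_len, seed = seed + 1)))
  health <- health_params(target_yield = target_yield,
                          mean_read_length = mean_read_length,
                          n_starting_channels = n_channels,
                          initial_saturation_fraction = initial_saturation)
  engine_new(ref, test_model(), health, scaling = test_scaling(),
             dwell = test_dwell(), n_channels = n_channels, seed = seed,
             mean_read_length = mean_read_length, noise_stdv = noise_stdv,
             gap_mean = gap_mean, keep_signal = keep_signal, ...)
}

# Write a minimal server INI + profile TOML pair; returns their paths.
test_config_files <- function(dir, ref_path, model_path, n_channels = 16,
                              extra_profile = character(0)) {
  ini <- file.path(dir, "server.ini")
  writeLines(c("[server]", "manager_port = 9000", "data_port = 9001",
               "position_name = TEST-1", "[device]",
               sprintf("n_channels = %d", n_channels), "sample_rate = 4000"),
             ini)
  toml <- file.path(dir, "profile.toml")
  writeLines(c("target_yield = 1000000000",
               "mean_read_length = 2000",
               sprintf('pore_model = "%s"', model_path),
               'chemistry = "R9"',
               "seed = 7",
               'output_format = "none"',
               extra_profile,
               "[[sample]]",
               'name = "syn"',
               sprintf('reference = "%s"', ref_path),
               "weight = 1"),
             toml)
  list(ini = ini, toml = toml)
}
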