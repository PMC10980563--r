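# Configuration: server INI + simulation-profile TOML.
#
# Two files configure a run. The INI holds software/sequencer plumbing
# (ports, TLS certificate paths, position name, channel count); the TOML
# "simulation profile" holds everything about the experiment being
# simulated (references and species proportions, read lengths, barcodes,
# pore model, target yield, output format). Unknown keys are hard errors:
# a typo in a profile must not silently change an experiment.
#
# No TOML parser ships with this R stack, so a minimal, documented subset
# is parsed here: comments, `[table]`, `[[array-of-tables]]`, and
# `key = value` with strings, numbers, booleans and single-line arrays.

# ---- TOML subset ------------------------------------------------------------

toml_scalar <- function(tok) {
  tok <- trimws(tok)
  if (grepl('^".*"$', tok)) return(gsub('^"|"$', "", tok))
  if (tok == "true") return(TRUE)
  if (tok == "false") return(FALSE)
  num <- suppressWarnings(as.numeric(tok))
  if (!is.na(num)) return(num)
  stop_config("cannot parse TOML value: %s", tok)
}

toml_value <- function(raw) {
  raw <- trimws(raw)
  if (startsWith(raw, "[")) {
    if (!endsWith(raw, "]")) stop_config("unterminated TOML array: %s", raw)
    inner <- trimws(substr(raw, 2, nchar(raw) - 1))
    if (!nzchar(inner)) return(list())
    toks <- strsplit(inner, ",", fixed = TRUE)[[1]]
    vals <- lapply(toks, toml_scalar)
    if (all(vapply(vals, is.character, NA)) || all(vapply(vals, is.numeric, NA))) {
      return(unlist(vals))
    }
    return(vals)
  }
  toml_scalar(raw)
}

strip_toml_comment <- function(line) {
  out <- character(1)
  inq <- FALSE
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == '"') inq <- !inq
    if (chars[i] == "#" && !inq) return(substr(line, 1, i - 1))
  }
  line
}

#' Parse a TOML file (documented subset)
#'
#' Supports comments, `[table]`, `[[array-of-tables]]` and `key = value`
#' lines with string/number/boolean scalars and single-line arrays — the
#' subset simulation profiles use.
#'
#' @param path TOML file path.
#' @return nested named list; array-of-table sections become unnamed lists.
#' @export
parse_toml <- function(path) {
  if (!file.exists(path)) stop_config("TOML file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  root <- list()
  target <- character(0)   # current table path
  is_array <- FALSE
  for (ln in lines) {
    ln <- trimws(strip_toml_comment(ln))
    if (!nzchar(ln)) next
    if (grepl("^\\[\\[.*\\]\\]$", ln)) {
      name <- trimws(gsub("^\\[\\[|\\]\\]$", "", ln))
      if (is.null(root[[name]])) root[name] <- list(list())
      root[[name]][[length(root[[name]]) + 1L]] <- list()
      target <- name; is_array <- TRUE
    } else if (grepl("^\\[.*\\]$", ln)) {
      name <- trimws(gsub("^\\[|\\]$", "", ln))
      if (is.null(root[[name]])) root[[name]] <- list()
      target <- name; is_array <- FALSE
    } else if (grepl("=", ln, fixed = TRUE)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      key <- trimws(substr(ln, 1, eq - 1))
      val <- toml_value(substr(ln, eq + 1, nchar(ln)))
      if (length(target) == 0L) {
        root[[key]] <- val
      } else if (is_array) {
        i <- length(root[[target]])
        root[[target]][[i]][[key]] <- val
      } else {
        root[[target]][[key]] <- val
      }
    } else {
      stop_config("cannot parse TOML line: %s", ln)
    }
  }
  root
}

toml_format_value <- function(v) {
  fmt1 <- function(x) {
    if (is.character(x)) paste0('"', x, '"')
    else if (is.logical(x)) tolower(as.character(x))
    else format(x, scientific = FALSE, trim = TRUE)
  }
  if (length(v) > 1L) {
    paste0("[", paste(vapply(v, fmt1, ""), collapse = ", "), "]")
  } else {
    fmt1(v)
  }
}

#' Serialize a flat-plus-array-of-tables list to TOML text
#' @param x named list: scalars/vectors at top level; a list of unnamed
#'   lists becomes `[[name]]` sections.
#' @param path output path.
#' @export
write_toml <- function(x, path) {
  out <- character(0)
  tables <- character(0)
  for (key in names(x)) {
    v <- x[[key]]
    if (is.list(v) && length(v) && is.null(names(v))) {
      tables <- c(tables, key)
    } else if (!is.null(v) && !(is.atomic(v) && length(v) == 0L)) {
      out <- c(out, paste(key, "=", toml_format_value(v)))
    }
  }
  for (key in tables) {
    for (entry in x[[key]]) {
      out <- c(out, "", paste0("[[", key, "]]"))
      for (k2 in names(entry)) {
        v2 <- entry[[k2]]
        if (!is.null(v2) && !(is.atomic(v2) && length(v2) == 0L)) {
          out <- c(out, paste(k2, "=", toml_format_value(v2)))
        }
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}

# ---- schema -----------------------------------------------------------------

PROFILE_GLOBAL_KEYS <- c(
  "target_yield", "mean_read_length", "initial_saturation_fraction",
  "pore_model", "chemistry", "bases_per_second", "seed", "output_format",
  "batch_size", "acceleration", "noise_stdv", "chunk_period", "gap_mean",
  "unblock_exit_samples", "length_shape", "experiment_id", "sample_id",
  "flow_cell_id", "barcode_fasta", "adaptor_signal_length", "stall_level",
  "amplicon_mode", "jitter", "sample")

PROFILE_SAMPLE_KEYS <- c("name", "reference", "weight", "mean_read_length",
                         "barcodes", "barcode_weights", "amplicons")

SERVER_KEYS <- list(server = c("manager_port", "data_port", "position_name",
                               "tls_cert", "tls_key"),
                    device = c("n_channels", "sample_rate"))

CHEMISTRY_SPEED <- c(R9 = 450, R10 = 400, RNA = 70)
CHEMISTRY_K <- list(R9 = c(5L, 6L), R10 = 9L, RNA = 5L)

check_keys <- function(got, allowed, where) {
  bad <- setdiff(got, allowed)
  if (length(bad)) {
    stop_config("unknown %s key(s): %s", where, paste(bad, collapse = ", "))
  }
}

#' Load and validate the two-file run configuration
#'
#' Reads the server INI and the simulation-profile TOML, applies defaults,
#' normalizes weights, and validates every key and referenced file.
#' Relative paths in the profile are resolved against the profile's
#' directory.
#'
#' @param ini_path server INI path.
#' @param toml_path simulation-profile TOML path.
#' @return list with `server` (ports, TLS paths, position, channel count)
#'   and `profile` (fully resolved simulation parameters), class
#'   `sim_config`.
#' @export
load_profile <- function(ini_path, toml_path) {
  if (!file.exists(ini_path)) stop_config("INI file not found: %s", ini_path)
  raw_ini <- ini::read.ini(ini_path)
  check_keys(names(raw_ini), names(SERVER_KEYS), "INI section")
  for (sec in names(raw_ini)) {
    check_keys(names(raw_ini[[sec]]), SERVER_KEYS[[sec]],
               sprintf("INI [%s]", sec))
  }
  srv <- raw_ini$server %||% list()
  dev <- raw_ini$device %||% list()
  server <- list(
    manager_port = as.integer(srv$manager_port %||% 10000),
    data_port = as.integer(srv$data_port %||% 10001),
    position_name = srv$position_name %||% "SIM-1",
    tls_cert = srv$tls_cert, tls_key = srv$tls_key,
    n_channels = as.integer(dev$n_channels %||% 512),
    sample_rate = as.numeric(dev$sample_rate %||% 4000))
  if (server$manager_port == server$data_port) {
    stop_config("manager_port and data_port must differ")
  }
  if (any(c(server$manager_port, server$data_port) < 1) ||
      any(c(server$manager_port, server$data_port) > 65535)) {
    stop_config("ports must be in 1..65535")
  }
  if (server$n_channels < 1) stop_config("n_channels must be >= 1")
  for (p in c(server$tls_cert, server$tls_key)) {
    if (!is.null(p) && nzchar(p) && !file.exists(p)) {
      stop_config("TLS file not found: %s", p)
    }
  }

  raw <- parse_toml(toml_path)
  check_keys(names(raw), PROFILE_GLOBAL_KEYS, "profile")
  base_dir <- dirname(normalizePath(toml_path))
  resolve <- function(p) {
    if (is.null(p) || !nzchar(p)) return(p)
    if (file.exists(p)) normalizePath(p) else file.path(base_dir, p)
  }
  chem <- raw$chemistry %||% "R9"
  if (!chem %in% names(CHEMISTRY_SPEED)) {
    stop_config("chemistry must be one of %s",
                paste(names(CHEMISTRY_SPEED), collapse = "/"))
  }
  profile <- list(
    target_yield = as.numeric(raw$target_yield %||% 1e9),
    mean_read_length = as.numeric(raw$mean_read_length %||% 10000),
    initial_saturation_fraction =
      as.numeric(raw$initial_saturation_fraction %||% 0.15),
    pore_model = resolve(raw$pore_model),
    chemistry = chem,
    bases_per_second = as.numeric(raw$bases_per_second %||%
                                    CHEMISTRY_SPEED[[chem]]),
    seed = as.numeric(raw$seed %||% 1),
    output_format = raw$output_format %||% "fast5",
    batch_size = as.numeric(raw$batch_size %||% 4000),
    acceleration = as.numeric(raw$acceleration %||% 1),
    noise_stdv = as.numeric(raw$noise_stdv %||% 0.15),
    chunk_period = as.numeric(raw$chunk_period %||% 1),
    gap_mean = as.numeric(raw$gap_mean %||% 0.5),
    unblock_exit_samples = as.numeric(raw$unblock_exit_samples %||% 0),
    length_shape = as.numeric(raw$length_shape %||% 2),
    experiment_id = raw$experiment_id %||% "experiment_1",
    sample_id = raw$sample_id %||% "sample_1",
    flow_cell_id = raw$flow_cell_id %||% "FC001",
    barcode_fasta = resolve(raw$barcode_fasta),
    adaptor_signal_length = as.numeric(raw$adaptor_signal_length %||% 100),
    stall_level = as.numeric(raw$stall_level %||% 1.5),
    amplicon_mode = isTRUE(raw$amplicon_mode),
    jitter = raw$jitter %||% "none")

  if (profile$target_yield <= 0) stop_config("target_yield must be > 0")
  if (profile$mean_read_length <= 0) stop_config("mean_read_length must be > 0")
  if (profile$initial_saturation_fraction < 0 ||
      profile$initial_saturation_fraction > 1) {
    stop_config("initial_saturation_fraction must be in [0, 1]")
  }
  if (!profile$output_format %in% c("fast5", "pod5", "none")) {
    stop_config("output_format must be fast5, pod5 or none")
  }
  if (profile$batch_size < 1) stop_config("batch_size must be >= 1")
  if (profile$acceleration < 1) stop_config("acceleration must be >= 1")
  if (!profile$jitter %in% c("none", "geometric")) {
    stop_config("jitter must be 'none' or 'geometric'")
  }
  if (is.null(raw$sample) || length(raw$sample) == 0L) {
    stop_config("profile defines no [[sample]] table")
  }
  samples <- lapply(raw$sample, function(s) {
    check_keys(names(s), PROFILE_SAMPLE_KEYS, "profile [[sample]]")
    if (is.null(s$reference)) stop_config("[[sample]] needs a reference path")
    ref <- resolve(s$reference)
    if (!file.exists(ref)) stop_config("reference FASTA not found: %s", ref)
    amp <- NULL
    if (!is.null(s$amplicons)) {
      amp <- resolve(s$amplicons)
      if (!file.exists(amp)) stop_config("amplicon BED not found: %s", amp)
    }
    if (!is.null(s$barcode_weights)) {
      if (length(s$barcode_weights) != length(s$barcodes)) {
        stop_config("barcode_weights length must match barcodes")
      }
      if (any(s$barcode_weights < 0) || all(s$barcode_weights == 0)) {
        stop_config("barcode_weights must be >= 0 with at least one > 0")
      }
      s$barcode_weights <- s$barcode_weights / sum(s$barcode_weights)
    }
    list(name = s$name %||% tools::file_path_sans_ext(basename(ref)),
         reference = ref, weight = as.numeric(s$weight %||% 1),
         mean_read_length = as.numeric(s$mean_read_length %||%
                                         profile$mean_read_length),
         barcodes = s$barcodes, barcode_weights = s$barcode_weights,
         amplicons = amp)
  })
  wts <- vapply(samples, `[[`, 0, "weight")
  if (any(wts < 0) || all(wts == 0)) {
    stop_config("sample weights must be >= 0 with at least one > 0")
  }
  for (i in seq_along(samples)) samples[[i]]$weight <- wts[i] / sum(wts)
  profile$sample <- samples

  if (!is.null(profile$pore_model)) {
    if (!file.exists(profile$pore_model)) {
      stop_config("pore model file not found: %s", profile$pore_model)
    }
  }
  uses_barcodes <- any(vapply(samples, function(s) length(s$barcodes) > 0, NA))
  if (uses_barcodes && is.null(profile$barcode_fasta)) {
    profile$barcode_fasta <- system.file("extdata",
                                         "synthetic_barcodes_nb12.fasta",
                                         package = "squigglesim")
  }
  if (profile$amplicon_mode &&
      !any(vapply(samples, function(s) !is.null(s$amplicons), NA))) {
    stop_config("amplicon_mode requires at least one sample with an amplicon BED")
  }
  structure(list(server = server, profile = profile), class = "sim_config")
}

#' Serialize a resolved profile back to TOML
#'
#' Together with [load_profile()] this is idempotent: loading the written
#' file reproduces the same resolved profile. Used to record provenance in
#' each run directory.
#'
#' @param profile the `profile` element of a `sim_config`.
#' @param path output TOML path.
#' @export
write_profile <- function(profile, path) {
  out <- profile
  out$sample <- lapply(profile$sample, function(s) {
    s[!vapply(s, is.null, NA)]
  })
  out <- out[!vapply(out, is.null, NA)]
  write_toml(out, path)
}

#' Validate chemistry/pore-model consistency
#' @param profile resolved profile.
#' @param model a [kmer_model()].
#' @export
check_chemistry <- function(profile, model) {
  ok <- CHEMISTRY_K[[profile$chemistry]]
  if (!model$k %in% ok) {
    stop_config("chemistry %s expects k in {%s} but model has k=%d",
                profile$chemistry, paste(ok, collapse = ","), model$k)
  }
  invisible(TRUE)
}
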