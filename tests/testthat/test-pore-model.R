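# Squiggle synthesis: k-mer tables, denormalization, dwell expansion.

test_that("k-mer tables parse, infer k, and reject malformed input", {
  path <- withr::local_tempfile(fileext = ".tsv")

  writeLines(c("AAAAA\t-1.0\t0.1", "AAAAC\t0.5\t0.1"), path)
  m <- read_kmer_model(path)
  expect_equal(m$k, 5)
  expect_equal(length(m$kmers), 2)
  expect_equal(unname(m$level_mean[match("AAAAA", m$kmers)]), -1.0)

  # header line is detected and skipped; missing stdv column fills a constant
  writeLines(c("kmer\tlevel_mean", "ACGTA\t0.25", "TTTTT\t-0.5"), path)
  m2 <- read_kmer_model(path, default_stdv = 0.33)
  expect_equal(m2$k, 5)
  expect_true(all(m2$level_stdv == 0.33))

  writeLines(c("AAAAA\t-1.0", "AAAAAC\t0.5"), path)
  expect_error(read_kmer_model(path), "inconsistent k-mer lengths")
  writeLines(c("AANAA\t-1.0"), path)
  expect_error(read_kmer_model(path), "non-ACGT")
  writeLines(character(0), path)
  expect_error(read_kmer_model(path), "empty")
  writeLines(c("AAAAA\t-1.0", "AAAAA\t0.5"), path)
  expect_error(read_kmer_model(path), "duplicate")
})

test_that("a full 4^9-entry R10-style table round-trips through the file dialect", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_kmer_model(make_synthetic_kmer_model(9, seed = 2), path)
  m <- read_kmer_model(path)
  expect_equal(m$k, 9)
  expect_equal(length(m$kmers), 262144)  # 4^9, counted independently
})

test_that("denormalization matches hand arithmetic and preserves order", {
  sc <- signal_scaling(signal_mean = 90, signal_stdv = 25)
  expect_equal(denormalize(0, sc), 90)
  expect_equal(denormalize(1, sc), 115)
  expect_equal(denormalize(-2, sc), 40)
  z <- sort(stats::rnorm(50))
  expect_false(is.unsorted(denormalize(z, signal_scaling())))
})

test_that("sequence_to_levels equals an independent sliding-window lookup", {
  m <- test_model()
  one <- sequence_to_levels("AAAAA", m)
  expect_length(one, 1)
  expect_equal(one, unname(m$level_mean[match("AAAAA", m$kmers)]))

  lv <- sequence_to_levels("AAAAAC", m)
  expect_equal(lv, unname(m$level_mean[match(c("AAAAA", "AAAAC"), m$kmers)]))

  # brute-force oracle: named-vector lookup over explicit substrings
  lookup <- stats::setNames(m$level_mean, m$kmers)
  for (seed in 1:5) {
    s <- random_seq(200, seed = seed)
    oracle <- vapply(1:(200 - m$k + 1),
                     function(i) lookup[[substr(s, i, i + m$k - 1)]], 0)
    expect_identical(sequence_to_levels(s, m), oracle)
  }
  expect_error(sequence_to_levels("ACG", m), "shorter")
})

test_that("noiseless synthesis equals per-k-mer block concatenation exactly", {
  m <- test_model()
  sc <- test_scaling()
  dw <- test_dwell(bases_per_second = 4000 / 9)  # samples_per_base = 9 exactly

  one <- levels_to_signal(0.7, dw, sc)
  expect_identical(one, rep.int(digitize_pa(denormalize(0.7, sc), sc), 9L))

  s <- random_seq(100, seed = 9)
  lv <- sequence_to_levels(s, m)
  got <- levels_to_signal(lv, dw, sc)
  # independent loop: each level repeated for its own dwell block
  spb <- dw$samples_per_base
  oracle <- unlist(lapply(seq_along(lv), function(i) {
    rep.int(digitize_pa(denormalize(lv[i], sc), sc),
            round(i * spb) - round((i - 1) * spb))
  }))
  expect_identical(got, oracle)
  expect_error(levels_to_signal(numeric(0), dw, sc), "empty")
})

test_that("length conservation and quantization round trip hold across dwells", {
  m <- test_model()
  sc <- test_scaling()
  for (bps in c(450, 400, 70)) {
    dw <- test_dwell(bases_per_second = bps)
    s <- random_seq(300, seed = bps)
    lv <- sequence_to_levels(s, m)
    sig <- levels_to_signal(lv, dw, sc)
    expect_lte(abs(length(sig) - round(length(lv) * dw$samples_per_base)), 1)
    # undigitize and z-normalize: recovers levels within one quantization step
    step_z <- sc$range / sc$digitisation / sc$signal_stdv
    per_sample <- (undigitize_pa(sig, sc) - sc$signal_mean) / sc$signal_stdv
    bounds <- round((0:length(lv)) * dw$samples_per_base)
    expanded <- rep.int(lv, diff(bounds))
    expect_true(all(abs(per_sample - expanded) <= step_z))
  }
})

test_that("noisy synthesis is seed-deterministic and seed-sensitive", {
  dw <- test_dwell()
  sc <- test_scaling()
  lv <- sequence_to_levels(random_seq(80, seed = 3), test_model())
  a <- levels_to_signal(lv, dw, sc, 0.15, squigglesim:::rng_stream(5))
  b <- levels_to_signal(lv, dw, sc, 0.15, squigglesim:::rng_stream(5))
  c <- levels_to_signal(lv, dw, sc, 0.15, squigglesim:::rng_stream(6))
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_error(levels_to_signal(lv, dw, sc, 0.15), "rng")
})
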