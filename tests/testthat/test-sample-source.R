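# Molecule sampling: lengths, positions, strands, amplicons, barcodes.

test_that("read lengths hit the configured mean, clamp, and replay by seed", {
  rng <- squigglesim:::rng_stream(1)
  draws <- vapply(1:50000, function(i) draw_read_length(10000, rng), 0)
  expect_lt(abs(mean(draws) - 10000) / 10000, 0.02)
  expect_true(all(draws >= 200))

  rng_small <- squigglesim:::rng_stream(2)
  small <- vapply(1:200, function(i) draw_read_length(50, rng_small), 0)
  expect_true(all(small >= 200))       # clamp floor
  expect_gt(mean(small == 200), 0.9)   # and it actually engages

  r1 <- squigglesim:::rng_stream(9); r2 <- squigglesim:::rng_stream(9)
  expect_identical(vapply(1:100, function(i) draw_read_length(5000, r1), 0),
                   vapply(1:100, function(i) draw_read_length(5000, r2), 0))
  expect_error(draw_read_length(0, rng), "mean_read_length")
})

test_that("reads truncate at contig ends and match the reference slice", {
  contig <- random_seq(1000, seed = 4)
  ref <- test_refset(c(chr1 = contig))
  rng <- squigglesim:::rng_stream(11)
  for (i in 1:100) {
    d <- draw_read(ref, 5000, rng)
    expect_lte(d$end, 1000)
    expect_gte(d$start, 0)
    slice <- substr(contig, d$start + 1, d$end)
    if (d$strand == "+") {
      expect_identical(d$sequence, slice)
    } else {
      expect_identical(d$sequence, squigglesim:::revcomp_chr(slice))
    }
    expect_equal(nchar(d$sequence), d$end - d$start)
  }
})

test_that("species are drawn by weight and starts are uniform", {
  ref <- reference_set(list(
    list(name = "sp1", weight = 9, contigs = c(a = random_seq(5000, 5))),
    list(name = "sp2", weight = 1, contigs = c(b = random_seq(5000, 6)))))
  rng <- squigglesim:::rng_stream(12)
  sp <- vapply(1:20000, function(i) draw_read(ref, 500, rng)$species, "")
  expect_lt(abs(mean(sp == "sp1") - 0.9), 0.01)

  # chi-square on start positions over 10 equal bins, single contig
  ref1 <- test_refset(c(chr = random_seq(10000, 7)))
  rng2 <- squigglesim:::rng_stream(13)
  starts <- vapply(1:20000, function(i) draw_read(ref1, 300, rng2)$start, 0L)
  bins <- table(cut(starts, breaks = seq(0, 10000, length.out = 11),
                    include.lowest = TRUE))
  p <- stats::chisq.test(as.vector(bins))$p.value
  expect_gt(p, 0.001)
})

test_that("ambiguity codes resolve to concrete bases deterministically", {
  ref <- test_refset(c(chr = paste0(strrep("ACGTN", 200), strrep("A", 200))))
  r1 <- squigglesim:::rng_stream(21); r2 <- squigglesim:::rng_stream(21)
  d1 <- draw_read(ref, 400, r1); d2 <- draw_read(ref, 400, r2)
  expect_identical(d1$sequence, d2$sequence)
  expect_false(grepl("[^ACGT]", d1$sequence))
})

test_that("amplicon draws span whole intervals and split by weight", {
  contig <- random_seq(2000, seed = 8)
  amp <- data.frame(contig = "chr1", start = c(100, 1200), end = c(600, 1900))
  ref <- reference_set(list(list(name = "s", weight = 1,
                                 contigs = c(chr1 = contig))), amplicons = amp)
  rng <- squigglesim:::rng_stream(14)
  draws <- lapply(1:10000, function(i) draw_amplicon(ref, rng))
  starts <- vapply(draws, `[[`, 0L, "start")
  expect_true(all(starts %in% c(100L, 1200L)))
  expect_true(all(vapply(draws, `[[`, 0L, "end")[starts == 100L] == 600L))
  expect_lt(abs(mean(starts == 100L) - 0.5), 0.02)

  one <- reference_set(list(list(name = "s", weight = 1,
                                 contigs = c(chr1 = contig))),
                       amplicons = amp[1, ])
  d <- draw_amplicon(one, rng)
  expect_equal(c(d$start, d$end), c(100L, 600L))

  expect_error(
    reference_set(list(list(name = "s", weight = 1,
                            contigs = c(chr1 = contig))),
                  amplicons = data.frame(contig = "chr1", start = 1500,
                                         end = 2600)),
    "outside contig")
  expect_error(draw_amplicon(test_refset(c(x = contig)), rng), "no amplicons")
})

test_that("barcode flanking has the exact composed layout and length", {
  m <- test_model(); sc <- test_scaling(); dw <- test_dwell()
  sig <- levels_to_signal(sequence_to_levels(random_seq(300, 15), m), dw, sc)

  # identity case: no padding, empty barcode sequence
  b0 <- barcode_set("bc0", "", weights = 1, adaptor_signal_length = 0)
  expect_identical(flank_with_barcode(sig, "bc0", b0, m, sc, dw), sig)

  bset <- barcode_set(c("bc01", "bc02"),
                      c(random_seq(24, 16), random_seq(24, 17)),
                      adaptor_signal_length = 50, stall_level = 1.5)
  out <- flank_with_barcode(sig, "bc01", bset, m, sc, dw)
  arm_len <- function(s) {
    n <- nchar(s) - m$k + 1
    round(n * dw$samples_per_base)
  }
  expect_length(out, length(sig) + 2 * 50 +
                  arm_len(bset$sequences[1]) +
                  arm_len(squigglesim:::revcomp_chr(bset$sequences[1])))
  pad_val <- digitize_pa(denormalize(1.5, sc), sc)
  expect_true(all(out[1:50] == pad_val))
  expect_true(all(utils::tail(out, 50) == pad_val))
  expect_error(flank_with_barcode(sig, "nope", bset, m, sc, dw), "unknown barcode")
})

test_that("degenerate barcode weights send every read to one barcode", {
  ref <- test_refset(c(chr = random_seq(3000, 18)))
  bset <- barcode_set(c("bc01", "bc02"), c(random_seq(24, 1), random_seq(24, 2)),
                      weights = c(1, 0))
  rng <- squigglesim:::rng_stream(19)
  bcs <- vapply(1:1000, function(i) draw_read(ref, 400, rng, barcodes = bset)$barcode, "")
  expect_true(all(bcs == "bc01"))
})
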