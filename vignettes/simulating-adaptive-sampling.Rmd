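---
title: "Simulating nanopore adaptive-sampling runs with squigglesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating nanopore adaptive-sampling runs with squigglesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squigglesim)
```

## What this package simulates, and why

Nanopore sequencers stream raw ionic current ("squiggle") while molecules
are still translocating, and the control software exposes that stream over
an API. Adaptive-sampling tools exploit this: they look at the first chunk
of each read, decide whether the molecule is on target, and either let it
finish or reverse the pore voltage to eject it ("unblock"), freeing the
pore for another molecule. Developing such tools against real flow cells is
expensive, and replaying pre-recorded runs is misleading because a rejected
read cannot be replaced by a new molecule — the recording just gets cut
into fragments, so no enrichment is ever observed.

squigglesim simulates the sequencer end to end: it draws molecules from a
weighted reference set, synthesizes signal from k-mer pore models, serves
that signal chunk-by-chunk in (optionally accelerated) real time, honours
unblock and stop-receiving actions mid-read, models flow-cell decay, and
writes multi-read FAST5 plus a ground-truth sidecar. Because unblocked
molecules are genuinely replaced by new draws, adaptive sampling produces
real enrichment in simulation, which is the behaviour client software needs
to be tested against.

The signal is deliberately not a faithful reproduction of pore physics.
It is a clean, alignable facsimile: good enough to exercise every
real-time control path, not a substitute for real data in basecaller or
signal-analysis research.

## The squiggle model

A k-mer pore model maps each k-mer to a z-score-normalized current level.
A sequence of $n$ bases yields $n-k+1$ levels by sliding a k-wide window
(left-aligned: level $i$ is emitted while bases $i..i+k-1$ occupy the
pore; any fixed convention is internally consistent and this one makes the
sliding-window oracle in the tests exact). Levels are denormalized to
picoamps as

$$\mathrm{pA} = z \cdot \sigma_{\mathrm{signal}} + \mu_{\mathrm{signal}}$$

and quantized to integer DAC counts with
`clamp(round(pA * digitisation / range - offset), 0, digitisation - 1)`.

Tunable parameters, defaults, and reasons:

* `signal_mean` = 90 pA, `signal_stdv` = 20 pA. Chosen to put synthetic
  current in a plausible pore-current range; published models are z-score
  normalized so these are free constants, recorded in output metadata and
  configurable. They only need to be consistent between synthesis and any
  downstream consumer.
* `digitisation` = 8192, `range` = 1500 pA, `offset` = 0. Plumbing required
  by the FAST5 channel metadata contract; with these values one DAC step is
  ~0.18 pA, so quantization error (~0.009 z units) is far below the level
  noise.
* Translocation speed: 450 bases/s for R9-style models, 400 for R10, 70
  for RNA — the community-standard nominal rates. With the fixed 4 kHz
  acquisition rate this sets the dwell, `samples_per_base = 4000/speed`.
* Dwell jitter: `none` by default. Cumulative level boundaries are
  `round(i * samples_per_base)`, so total signal length is exact and
  synthesis is a deterministic function of the sequence — this is what
  makes bit-exact oracle tests possible. A `geometric` mode with the same
  mean dwell exists for more realistic dwell spread.
* `noise_stdv` = 0.15 z units of per-sample Gaussian level noise,
  configurable; 0 in every oracle test.

Ambiguity codes (N and friends) in references are resolved to concrete
bases uniformly at draw time from the run's seeded streams, because pore
models only define ACGT k-mers.

## Drawing molecules

Species are chosen proportional to configured weights; within a species,
contigs proportional to length (so per-base coverage is uniform); the
start uniformly on the contig; strand 50/50, with minus-strand reads
reporting the forward interval and a reverse-complemented sequence.
Read lengths are Gamma(shape 2) with the configured mean — a right-skewed
shape typical of nanopore libraries; only the mean is specified by the
profile, the shape is exposed and the floor is clamped at 200 bases.
Draws extending past a contig end are truncated there. Amplicon mode
instead picks one configured interval (uniformly or by weight) and spans
it exactly. All coordinates are 0-based half-open, matching BED.

Barcoded runs squiggle the forward barcode before the read and the
barcode's reverse complement after it, padded on both sides by a constant
"adaptor" stretch at a configurable stall level. Both arms are always
present; truncation of arms and barcode misassignment are out of scope.

## Flow-cell health

Channels die irreversibly ("saturation"). At run start a fraction
(default 0.15) is saturated immediately. After every read end — natural
or unblock — the channel saturates with probability

$$\min\left(1,\; \frac{\mu_{\mathrm{read}} \cdot N_{\mathrm{channels}}}{Y_{\mathrm{target}}} \cdot \frac{L}{10\,000}\right)$$

where the first factor is the per-read "base chance" and $L$ is the number
of bases the molecule actually translocated. Using translocated rather
than drawn length is a deliberate choice the source description leaves
open: an unblocked molecule occupies the pore only briefly, and adaptive
sampling's whole benefit is that rejecting reads spends less pore life.

The $L/10\,000$ scaling makes expected total yield equal the target only
when mean read length is near 10 kb (expected bases per channel before
death are $10\,000/\mathrm{base\ chance}$ regardless of the length
distribution). The formula is implemented exactly as stated, and the yield
calibration test is asserted only in that regime. Probabilities are clamped
to 1 because the formula can exceed it for long reads or small targets.

## The real-time engine

The engine is clock-agnostic: `engine_tick(e, t)` advances every channel
to simulated time `t`, so tests and accelerated runs drive a virtual clock
while `engine_run(..., realtime = TRUE, acceleration = a)` slaves simulated
time to the wall clock. Within one tick a channel may finish a read, wait
its inter-read gap (exponential, mean 0.5 s — a pore is not 100% duty
cycle; configurable), and start the next, so coarse polling loses no
throughput.

Each channel owns an independent RNG stream derived from
`(master_seed, channel)`, and each read owns a noise stream seeded from
its channel's stream. Consequences: actions on one channel never perturb
another channel's future, and a run with a fixed seed and scripted actions
is byte-reproducible.

Signal is materialized lazily. At draw time only the level vector is
computed; DAC samples are generated in order, from the read's own stream,
for exactly the ranges that serving or output observes. Because noise is
consumed strictly left-to-right from a private stream, the result is
bit-identical to one-shot synthesis — a property the engine tests assert
rather than assume.

Serving follows the live-reads contract: `engine_get_chunks()` returns
signal accrued since the last call per sequencing channel, capped at one
chunk period (default 1 s, i.e. 4000 samples) with the remainder carried
over; reads under `stop_receiving` are omitted while they sequence to
completion. `unblock` truncates the read at its served cursor (plus a
configurable exit tail, default 0 samples for test exactness), finalizes
it with end reason `unblock_mux_change`, and blocks the channel for the
requested unblock duration. Stale actions (an earlier read number) and
actions on finished reads are acknowledged as failures without side
effects. At run end, in-flight reads are flushed with end reason
`mux_change`. Chunk classification is reduced to a single `strand` class.

## The control API

The live-reads and metadata endpoints are exposed at message level —
setup (channel range) before anything else, chunk batches filtered to the
session's range without consuming other sessions' cursors, per-action
acknowledgements — plus a line-delimited JSON-over-TCP transport for
out-of-process clients. The original control software speaks gRPC; no
gRPC or protobuf stack exists in this R environment, so the wire format
differs while the message semantics, ordering rules and failure modes are
kept. The equivalence test drives the same decisions once through the API
surface and once through direct engine calls and requires identical final
read sets. TLS is out of scope for the transport.

## Output

Reads batch into multi-read FAST5 (HDF5) files of 4000 reads (profile
parameter), the last batch partial, inside
`<out>/<experiment>/<sample>/<flowcell>_<runid8>/fast5/`. Each read group
carries the raw signal (int16, gzip), read attributes (id, number, start,
duration, end reason) and the `channel_id`/`tracking_id` attribute groups
consumers expect. POD5 has no R implementation available here and is
declined explicitly rather than half-written. Every run also writes a
tab-separated truth sidecar (origin, strand, barcode, end reason, drawn
and translocated bases per read) and a JSON summary; the sidecar is what
analyses and the acceptance experiment consume, and it is exact regardless
of whether signal is kept.

## Configuration

Two files: a server INI (ports, TLS paths, position name, channel count,
sample rate) and a simulation-profile TOML (global run parameters plus one
`[[sample]]` table per species: reference, weight, read length, barcodes,
amplicons). Unknown keys are hard errors — a typo must not silently change
an experiment. The resolved profile is serialized into every run directory,
and load–write–load is idempotent. R has no TOML parser installed, so a
minimal documented subset (tables, array-of-tables, scalars, single-line
arrays, comments) is parsed by the package itself.

## What the synthetic world does and does not establish

The fixture generator produces uniform-composition random genomes at a
requested GC, synthetic k-mer tables with i.i.d. levels, and synthetic
barcode sets. These exercise every contract in the package — coordinates,
strands, dwell arithmetic, chunk timing, decay, reproducibility — but they
contain no repeats, no compositional structure, no real pore noise, and
the models carry no real pore physics (all synthetic artifacts are labelled
as such). A green suite therefore establishes the simulator's mechanical
and statistical contracts, not biological realism of the signal.

The oracle adaptive-sampling client decides from simulation truth rather
than basecalling — deliberately, so the simulator contract is tested in
isolation from basecaller availability — and refuses to run on an engine
that does not expose truth, preventing accidental use as a real classifier.

## The enrichment experiment

`run_enrichment_experiment()` fixes the stated world once: a 5 Mb synthetic
genome with 4% of its length on-target, 512 channels, 28 kb mean reads,
R9-style 5-mer model at 450 bases/s, 1 s decision chunks, 0.5 s mean gaps,
15% initial saturation, target yield 5e8 bases, 120 simulated seconds,
control and adaptive runs from identical seeds. Back-of-envelope, a 28 kb
read occupies a pore ~62 s while a rejected read costs ~1–2 s plus the gap,
so the on-target base rate per channel rises from
$0.04 \times 28000 / 62.7 \approx 18$ b/s to roughly
$1120 / 4 \approx 280$ b/s — an expected fold change in the mid-teens,
which is what the acceptance script recomputes from the sidecars at run
time. The 120 s window and 5e8 target keep the paired runs within desk-scale
CPU budgets; medians are compared over naturally-ended and unblocked reads
only, since reads cut by the end of the window would otherwise bias both
arms' length distributions downward.

## Known limitations

* Signal realism: no stalls, flicker, adapter current profiles, or
  basecall-accuracy guarantees.
* No chimeras, barcode cross-talk, mux scans, or pore-state telemetry
  beyond active/saturated.
* The TCP transport is plaintext JSON, not gRPC/TLS; in-process use is the
  primary surface.
* POD5 output and basecalled FASTQ are not produced.
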