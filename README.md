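# squigglesim

Real-time simulation of Oxford Nanopore sequencing runs, for developing and
testing adaptive-sampling ("read-until") software without touching a flow
cell.

## The problem

Adaptive-sampling tools watch the first chunk of raw current from every
read and decide, while the molecule is still in the pore, whether to let it
finish or to eject it ("unblock") and free the pore for another molecule.
Testing such tools is awkward: real runs burn consumables, and replaying a
recorded run cannot show enrichment because a rejected read is merely cut
into fragments — it is never replaced by a new molecule. A useful simulator
has to *be* the sequencer: draw molecules, stream their signal at the
acquisition rate, honour unblock requests mid-read, lose pores over time,
and write files the downstream ecosystem can read.

## What the simulator does

- **Squiggle synthesis from k-mer pore models.** A sliding k-wide window
  maps sequence to z-score current levels; each level is held for its dwell
  at the 4 kHz acquisition rate (translocation 450/400/70 bases/s for
  R9/R10/RNA-style chemistries), Gaussian level noise is added, and levels
  are denormalized and digitized:

  `pA = z * signal_stdv + signal_mean`,
  `DAC = clamp(round(pA * digitisation / range - offset), 0, digitisation - 1)`

- **Molecule sampling** from weighted multi-species references: species by
  weight, contig by length, uniform starts, Gamma(shape 2) lengths around a
  configured mean, 50/50 strands, optional amplicon mode and barcode
  flanking (forward arm + read + reverse-complement arm, adaptor padding).

- **Flow-cell health.** A fraction of channels (default 15%) is dead at
  start; after every read a channel saturates with probability
  `min(1, mean_read_length * n_channels / target_yield * L / 10000)` where
  `L` is the bases actually translocated — long reads wear pores faster,
  and unblocked reads barely wear them at all.

- **A real-time engine** (virtual or wall clock) serving per-channel signal
  chunks, applying `unblock` / `stop_receiving` actions with per-action
  acknowledgements, and finalizing every read with an end reason
  (`signal_positive`, `unblock_mux_change`, `mux_change`).

- **A sequencer-control-style API**: live-reads sessions (setup, chunk
  batches, action acks) and metadata endpoints (positions, flow-cell info,
  acquisition counters), in-process or over line-delimited JSON/TCP.

- **Output**: multi-read FAST5 batches of 4000 reads in a MinKNOW-style
  directory tree, a tab-separated ground-truth sidecar (origin, strand,
  end reason, translocated bases per read), and a JSON run summary.

Runs are configured by a server INI plus a simulation-profile TOML, and are
byte-reproducible given a seed and a scripted client.

## Worked example

Enrich a 5 kb plasmid against a 20 kb background chromosome using the
bundled example configuration and the truth-driven oracle client:

```r
library(squigglesim)
ini  <- system.file("extdata", "example_server.ini",  package = "squigglesim")
prof <- system.file("extdata", "example_profile.toml", package = "squigglesim")

client <- oracle_client("plasmid_A")   # unblock everything else at first chunk
res <- simulate_run(ini, prof, duration_s = 20, out_dir = tempdir(),
                    client = client, seed = 42)

truth <- read_truth_sidecar(res$output$sidecar)
table(truth$end_reason)
aggregate(translocated_bases ~ contig, truth, sum)
```

Output from this exact run:

```
reads finished: 4568   yield: 2790019 bases

        mux_change    signal_positive unblock_mux_change
               216                777               3575

     contig translocated_bases
1   chrom_B            1009379
2 plasmid_A            1780640
FAST5 batches: 2
```

Reading it: 3575 reads were rejected at their first chunk
(`unblock_mux_change`), 777 sequenced to completion, 216 were still in the
pore when the 20-second window closed. The plasmid is 20% of the genome but
received 64% of the bases — the pore time freed by rejecting chromosomal
reads was spent on new draws, which is precisely the behaviour replay-based
testing cannot show. Two FAST5 files appear because batches close every
4000 reads.

A thin CLI wraps the same functions
(`inst/cli/squigglesim simulate|make-reference|squiggle|serve`).

## Acceptance script

`scripts/acceptance.R` recomputes the headline enrichment result from
scratch at desk scale: it generates a synthetic 5 Mb genome with 4% of its
length on-target, runs paired control and adaptive simulations (512
channels, 28 kb mean reads, identical seeds, oracle client rejecting
off-target reads at their first 1 s chunk), and reports the on-target
yield fold change between the two runs:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Runtime is a few minutes on one CPU; results land in the JSON given by
`--out`.
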