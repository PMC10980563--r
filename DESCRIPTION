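Package: squigglesim
Title: Real-Time Simulation of Nanopore Adaptive-Sampling Sequencing Runs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates Oxford Nanopore sequencing runs in real time. Synthesizes
    raw ionic-current signal ("squiggle") from any reference genome using k-mer
    pore models, serves the signal chunk-by-chunk over a sequencer-control style
    live-reads API so adaptive-sampling clients can unblock reads in flight,
    models flow-cell channel saturation and yield decay across a run, and writes
    base-caller-compatible multi-read FAST5 output together with a ground-truth
    sidecar for download-free verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    rhdf5,
    ini,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
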