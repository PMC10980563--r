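target_yield = 1000000000
mean_read_length = 10000
initial_saturation_fraction = 0.15
pore_model = "synthetic_r9_5mer_model.tsv"
chemistry = "R9"
seed = 1
output_format = "fast5"
batch_size = 4000

[[sample]]
name = "example"
reference = "example_reference.fasta"
weight = 1
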