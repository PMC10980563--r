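chrom_B	1000	1500
chrom_B	9000	9600
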