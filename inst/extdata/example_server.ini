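[server]
manager_port = 10000
data_port = 10001
position_name = SIM-1
[device]
n_channels = 512
sample_rate = 4000
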