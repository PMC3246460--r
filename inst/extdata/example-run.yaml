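# Example dynloop run configuration (see ?dl_load_config)
n: 120
cutoff: 20
p_form: 0.03
lifetime: 100
stage1: 300000
stage2: 600000
sampling: 100000
stride: 2500
seed: 42
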