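# standard SOLiD alignment-model parameters
p_snp: 0.0085
p_indel: 0.0015
p_err: 0.02
p_s: 0.05
err_start: 0.01
err_end: 0.1
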