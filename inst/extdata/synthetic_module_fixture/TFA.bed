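chr1	7600	7800
chr1	48000	48200
chr1	67000	67600
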