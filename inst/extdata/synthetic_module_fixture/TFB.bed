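chr1	12400	12600
chr1	52500	52700
chr1	70000	70100
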