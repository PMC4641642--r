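chr1	30100	30200
chr1	90000	90010
chr1	110000	110050
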