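chr1	9000	9100
chr1	89000	89200
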