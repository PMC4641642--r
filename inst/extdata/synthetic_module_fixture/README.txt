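Synthetic hand-built fixture for the module gene-assignment rule.
Six genes with TSSs 20 kb apart on one chromosome and five regulators
(TFA..TFE) whose peaks were placed by hand relative to the +/-2500 bp
promoter windows, including one peak (TFB, 52500-52700) that exactly abuts
a window to exercise the half-open convention. Not derived from any real
ChIP or annotation data.
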