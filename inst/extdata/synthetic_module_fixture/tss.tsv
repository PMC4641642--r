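gene	chrom	strand	tss
G1	chr1	+	10000
G2	chr1	-	30000
G3	chr1	+	50000
G4	chr1	-	70000
G5	chr1	+	90000
G6	chr1	+	110000
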