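site_id	chrom	strand	coord	gene	region
iA	chr1	+	1100	gA	intron
uA	chr1	+	1500	gA	3UTR
iB	chr1	+	2100	gB	intron
uB	chr1	+	2500	gB	3UTR
u1C	chr1	+	3100	gC	3UTR
u2C	chr1	+	3500	gC	3UTR
iD	chr1	+	4100	gD	intron
uD	chr1	+	4500	gD	3UTR
i1E	chr1	+	5100	gE	intron
i2E	chr1	+	5300	gE	intron
uE	chr1	+	5500	gE	3UTR
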