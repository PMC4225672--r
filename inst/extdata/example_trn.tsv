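regulator	target	regulator_class	mode	evidence
# synthetic miniature of a curated regulator->target table (not real data)
sigA	ccpA	sigma	activation	strong
sigA	ackA	sigma	activation	strong
sigA	abrB	sigma	activation	strong
sigA	hrcA	sigma	activation	strong
sigA	spo0A	sigma	activation	weak
ccpA	ackA	TF	repression	strong
ccpA	gntR	TF	repression	strong
ccpA	acsA	TF	repression	strong
gntR	gntP	TF	repression	strong
hrcA	hrcA	TF	repression	strong
hrcA	grpE	TF	repression	strong
abrB	spo0A	TF	repression	strong
spo0A	abrB	TF	repression	strong
spo0A	spoIIE	TF	activation	strong
abrB	spoIIE	TF	repression	strong
sigB	katE	sigma	activation	strong
sigB	gspA	sigma	activation	weak
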