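name	pattern	note
TATA-box	TATAAA	core promoter element around -30; dictionary default - verify against PlantCARE
CAAT-box	CCAAT	common enhancer element; dictionary default - verify against PlantCARE
G-box	CACGTG	light-responsive element; dictionary default - verify against PlantCARE
CCGTCC-box	CCGTCC	meristem-specific activation; dictionary default - verify against PlantCARE
ARE	AAACCA	anaerobic induction element; dictionary default - verify against PlantCARE
ERE	ATTTCAAA	ethylene-responsive element; dictionary default - verify against PlantCARE
HSE	AAAAAATTTC	heat-responsive element; dictionary default - verify against PlantCARE
CAT-box	GCCACT	meristem expression element; dictionary default - verify against PlantCARE
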