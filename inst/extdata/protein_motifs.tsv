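name	pattern	max_mismatches	note
KVGGL	KVGGL	0	K-X-G-G-L catalytic/substrate-binding motif, valine variant (named in text)
KTGGL	KTGGL	0	K-X-G-G-L catalytic/substrate-binding motif, threonine variant (named in text)
ITRLT	ITRLT	0	beta-sheet irregular loop near the ADP-binding pocket (named in text)
FEPCGLT	FEPCGLT	0	irregular loop of the ADP-binding pocket (named in text)
AER	AER	0	linker between carbohydrate-binding domains 1 and 2 (named in text)
KAEMK	KAEMK	1	linker between carbohydrate-binding domains 2 and 3; M->T variant in dicots
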