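species	maize	wheat	barley	rice	sorghum	brachypodium	soybean
maize
wheat	0.320
barley	0.321	0.062
rice	0.358	0.35	0.343
sorghum	0.076	0.308	0.317	0.357
brachypodium	0.307	0.178	0.178	0.343	0.299
soybean	0.518	0.531	0.530	0.48	0.515	0.533
arabidopsis	0.544	0.565	0.565	0.538	0.542	0.569	0.404
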