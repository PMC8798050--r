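unit	level	described	motus_2pct	motus_5pct
Metriorrhynchina	subtribe	895	1852	1445
Cautirina	subtribe	641	456	369
Metanoeina	subtribe	38	37	34
Australian_region	region	639	1608	1239
Wallacea	region	176	184	171
Philippines	region	104	33	33
Continental_Asia	region	404	416	330
Afrotropical_region	region	231	104	94
Australia	subregion	196	167	131
New_Guinea	subregion	423	1434	1105
Solomon_Islands	subregion	21	9	9
Sundaland	subregion	261	247	202
Indo_Burma	subregion	74	63	53
China_Japan	subregion	55	87	70
India	subregion	37	19	18
Sub_Saharan_Africa	subregion	178	74	65
Madagascar	subregion	53	30	29
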