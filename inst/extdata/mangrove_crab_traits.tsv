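species	family	distribution_range	habitat	spawnings_yr	spawning_zone	pld_days	density_m2	max_cw_mm	eggs_per_spawning	coverage
Uca_inversa	Ocypodidae	EAM	Littoral_fringe	10	Littoral_fringe	26	7.77	NA	1600	0.225
Uca_occidentalis	Ocypodidae	WIO	Littoral_fringe	12	Littoral_fringe	28	12.6	NA	2400	0.225
Uca_hesperiae	Ocypodidae	WIO	Sublittoral_fringe	12	Sublittoral_fringe	26	4.75	NA	1750	0.225
Perisesarma_guttatum	Sesarmidae	EAM	Eulittoral	12	Eulittoral	23	1.4	NA	8200	0.225
Neosarmatium_africanum	Sesarmidae	EAM	Littoral_fringe	4	Littoral_fringe	29	0.59	NA	56700	0.225
Scylla_serrata	Portunidae	IPO	Eulittoral_sublittoral	12	Oceanic_platform	26	0.08	NA	2000000	0.225
Cardisoma_carnifex	Gecarcinidae	IPO	Supralittoral	2	Sublittoral_fringe	25	0.725	NA	695000	0.225
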