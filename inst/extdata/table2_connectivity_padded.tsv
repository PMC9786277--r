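drug	score
Chlorprothixene	88.76
Sirolimus	87.8
Dihydroergocristine	84.11
Papaverine	83.98
Tamoxifen	80.92
Palbociclib	8e+01
Tacrolimus	64.55
Tretinoin	41.2
Minoxidil	-12.35
Quinidine	-77.4
Dasatinib	1e+02
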