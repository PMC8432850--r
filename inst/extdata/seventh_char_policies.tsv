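cm_subcategory	condition	value
S065		0
S065	loc_gt24h_return	5
S065	loc_gt24h_no_return	6
S000		X
S060		X
S020		X
S061		X
S005		X
S022		X
S024		X
S026		X
S040		X
S202		X
S2205		X
S224		X
S272		X
S250		X
S301		X
S360		X
S361		X
S365		X
S350		X
S600		X
S525		X
S720		X
S721		X
S781		X
S381		X
T140		X
T202		X
T243		X
T314		X
T317		X
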