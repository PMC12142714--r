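species	status	country	admin_region	feral
Homalodisca vitripennis	native	United States	Texas	FALSE
Homalodisca vitripennis	expanded	United States	California	FALSE
Vespula vulgaris	native	United Kingdom		FALSE
Vespula vulgaris	expanded	New Zealand		FALSE
Pieris rapae	native	United Kingdom		FALSE
Pieris rapae	expanded	United States		FALSE
Haemaphysalis longicornis	native	China		FALSE
Haemaphysalis longicornis	expanded	New Zealand		FALSE
Harmonia axyridis	native	Japan		FALSE
Harmonia axyridis	expanded	United Kingdom		FALSE
Diaphorina citri	native	Taiwan		FALSE
Diaphorina citri	expanded	Uruguay		FALSE
Diaphorina citri	expanded	United States		FALSE
Vespula germanica	native	United Kingdom		FALSE
Vespula germanica	expanded	New Zealand		FALSE
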