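class	name
RTX	RITUXIMAB
RTX	RITUXAN
RTX	MABTHERA
RTX	TRUXIMA
RTX	RUXIENCE
CTX	CYCLOPHOSPHAMIDE
CTX	CYTOXAN
CTX	ENDOXAN
PPI	OMEPRAZOLE
PPI	PANTOPRAZOLE
PPI	ESOMEPRAZOLE
PPI	LANSOPRAZOLE
PPI	RABEPRAZOLE
PPI	DEXLANSOPRAZOLE
STATIN	ATORVASTATIN
STATIN	SIMVASTATIN
STATIN	ROSUVASTATIN
STATIN	PRAVASTATIN
STATIN	LOVASTATIN
STATIN	PITAVASTATIN
STATIN	FLUVASTATIN
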