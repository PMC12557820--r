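pt
Pneumonia
Sepsis
Renal failure
Renal impairment
Vanishing bile duct syndrome
Cytomegalovirus infection
Hepatitis acute
Jaundice
Cholestasis
Infection
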