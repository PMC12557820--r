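pt	soc
Hepatic function abnormal	Hepatobiliary disorders
Liver disorder	Hepatobiliary disorders
Drug-induced liver injury	Hepatobiliary disorders
Jaundice	Hepatobiliary disorders
Cholestasis	Hepatobiliary disorders
Hepatitis acute	Hepatobiliary disorders
Vanishing bile duct syndrome	Hepatobiliary disorders
Pneumonia	Infections and infestations
COVID-19	Infections and infestations
Infection	Infections and infestations
Sepsis	Infections and infestations
Cytomegalovirus infection	Infections and infestations
Urinary tract infection	Infections and infestations
Diarrhoea	Gastrointestinal disorders
Nausea	Gastrointestinal disorders
Vomiting	Gastrointestinal disorders
Abdominal discomfort	Gastrointestinal disorders
Fatigue	General disorders and administration site conditions
Illness	General disorders and administration site conditions
Condition aggravated	General disorders and administration site conditions
Pyrexia	General disorders and administration site conditions
Headache	Nervous system disorders
Dizziness	Nervous system disorders
Hepatic enzyme increased	Investigations
Alanine aminotransferase increased	Investigations
Blood creatinine increased	Investigations
Renal impairment	Renal and urinary disorders
Renal failure	Renal and urinary disorders
Dyspnoea	Respiratory, thoracic and mediastinal disorders
Cough	Respiratory, thoracic and mediastinal disorders
Rash	Skin and subcutaneous tissue disorders
Alopecia	Skin and subcutaneous tissue disorders
Hypertension	Vascular disorders
Arthralgia	Musculoskeletal and connective tissue disorders
Myalgia	Musculoskeletal and connective tissue disorders
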