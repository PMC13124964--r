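pt	soc	background_prob
Product residue present	Product issues	0.002
Medication residue present	Product issues	0.001
Product solubility abnormal	Product issues	0.001
Product physical issue	Product issues	0.002
Product substitution issue	Product issues	0.003
Drug ineffective	General disorders and administration site conditions	0.060
Fatigue	General disorders and administration site conditions	0.080
Death	General disorders and administration site conditions	0.030
Drug dose omission	Injury, poisoning and procedural complications	0.020
Product dispensing error	Injury, poisoning and procedural complications	0.010
Maternal exposure during pregnancy	Injury, poisoning and procedural complications	0.010
Fall	Injury, poisoning and procedural complications	0.030
Nausea	Gastrointestinal disorders	0.080
Vomiting	Gastrointestinal disorders	0.050
Diarrhoea	Gastrointestinal disorders	0.050
Abdominal discomfort	Gastrointestinal disorders	0.020
Abdominal pain	Gastrointestinal disorders	0.030
Dysphagia	Gastrointestinal disorders	0.010
Retching	Gastrointestinal disorders	0.005
Malabsorption	Gastrointestinal disorders	0.002
Blood creatinine increased	Investigations	0.020
Blood potassium increased	Investigations	0.008
Urine pH increased	Investigations	0.002
Flank pain	Renal and urinary disorders	0.008
Pollakiuria	Renal and urinary disorders	0.006
Proteinuria	Renal and urinary disorders	0.008
Nephrolithiasis	Renal and urinary disorders	0.010
Hyperkalaemia	Metabolism and nutrition disorders	0.010
Decreased appetite	Metabolism and nutrition disorders	0.020
Palpitations	Cardiac disorders	0.020
Arrhythmia	Cardiac disorders	0.010
Headache	Nervous system disorders	0.090
Dizziness	Nervous system disorders	0.070
Rash	Skin and subcutaneous tissue disorders	0.050
Pruritus	Skin and subcutaneous tissue disorders	0.030
Oropharyngeal pain	Respiratory, thoracic and mediastinal disorders	0.015
Throat irritation	Respiratory, thoracic and mediastinal disorders	0.010
Dyspnoea	Respiratory, thoracic and mediastinal disorders	0.040
Insomnia	Psychiatric disorders	0.040
Anxiety	Psychiatric disorders	0.040
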