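pt	soc
Product residue present	Product issues
Medication residue present	Product issues
Product solubility abnormal	Product issues
Product physical issue	Product issues
Product substitution issue	Product issues
Drug ineffective	General disorders and administration site conditions
Fatigue	General disorders and administration site conditions
Death	General disorders and administration site conditions
Drug dose omission	Injury, poisoning and procedural complications
Product dispensing error	Injury, poisoning and procedural complications
Maternal exposure during pregnancy	Injury, poisoning and procedural complications
Fall	Injury, poisoning and procedural complications
Nausea	Gastrointestinal disorders
Vomiting	Gastrointestinal disorders
Diarrhoea	Gastrointestinal disorders
Abdominal discomfort	Gastrointestinal disorders
Abdominal pain	Gastrointestinal disorders
Dysphagia	Gastrointestinal disorders
Retching	Gastrointestinal disorders
Malabsorption	Gastrointestinal disorders
Blood creatinine increased	Investigations
Blood potassium increased	Investigations
Urine pH increased	Investigations
Flank pain	Renal and urinary disorders
Pollakiuria	Renal and urinary disorders
Proteinuria	Renal and urinary disorders
Nephrolithiasis	Renal and urinary disorders
Hyperkalaemia	Metabolism and nutrition disorders
Decreased appetite	Metabolism and nutrition disorders
Palpitations	Cardiac disorders
Arrhythmia	Cardiac disorders
Headache	Nervous system disorders
Dizziness	Nervous system disorders
Rash	Skin and subcutaneous tissue disorders
Pruritus	Skin and subcutaneous tissue disorders
Oropharyngeal pain	Respiratory, thoracic and mediastinal disorders
Throat irritation	Respiratory, thoracic and mediastinal disorders
Dyspnoea	Respiratory, thoracic and mediastinal disorders
Insomnia	Psychiatric disorders
Anxiety	Psychiatric disorders
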