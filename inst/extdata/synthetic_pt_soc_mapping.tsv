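preferred_term	soc
Pyrexia	General disorders and administration site conditions
Crying	General disorders and administration site conditions
Chills	General disorders and administration site conditions
Malaise	General disorders and administration site conditions
Pain	General disorders and administration site conditions
Swelling	General disorders and administration site conditions
Peripheral swelling	General disorders and administration site conditions
Oedema peripheral	General disorders and administration site conditions
Injection site erythema	General disorders and administration site conditions
Injection site swelling	General disorders and administration site conditions
Vaccination site reaction	General disorders and administration site conditions
Vaccination site oedema	General disorders and administration site conditions
Vaccination site nodule	General disorders and administration site conditions
Vaccination site erythema	General disorders and administration site conditions
Vaccination site pain	General disorders and administration site conditions
Hypotonic-hyporesponsive episode	Nervous system disorders
Hypotonia	Nervous system disorders
Somnolence	Nervous system disorders
Headache	Nervous system disorders
Dizziness	Nervous system disorders
Gait disturbance	Nervous system disorders
Convulsion	Nervous system disorders
Vomiting	Gastrointestinal disorders
Diarrhoea	Gastrointestinal disorders
Melaena	Gastrointestinal disorders
Pallor	Vascular disorders
Cyanosis	Vascular disorders
Apnoea	Respiratory, thoracic and mediastinal disorders
Respiratory rate increased	Respiratory, thoracic and mediastinal disorders
Bronchiolitis	Infections and infestations
Decreased appetite	Metabolism and nutrition disorders
Restlessness	Psychiatric disorders
Irritability	Psychiatric disorders
Screaming	Psychiatric disorders
Erythema	Skin and subcutaneous tissue disorders
Urticaria	Skin and subcutaneous tissue disorders
Pain in extremity	Musculoskeletal and connective tissue disorders
Autopsy	Surgical and medical procedures
Resuscitation	Surgical and medical procedures
Cardiac arrest	Cardiac disorders
Sudden infant death syndrome	Congenital, familial and genetic disorders
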