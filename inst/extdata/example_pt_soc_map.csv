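"pt","soc"
"Amyloid related imaging abnormality-oedema/effusion","Nervous system disorders"
"Amyloid related imaging abnormality-microhaemorrhages and haemosiderin deposits","Nervous system disorders"
"Cerebral microhaemorrhage","Nervous system disorders"
"Brain oedema","Nervous system disorders"
"Headache","Nervous system disorders"
"Dizziness","Nervous system disorders"
"Seizure","Nervous system disorders"
"Memory impairment","Nervous system disorders"
"Somnolence","Nervous system disorders"
"Confusional state","Psychiatric disorders"
"Disorientation","Psychiatric disorders"
"Anxiety","Psychiatric disorders"
"Insomnia","Psychiatric disorders"
"Nausea","Gastrointestinal disorders"
"Diarrhoea","Gastrointestinal disorders"
"Vomiting","Gastrointestinal disorders"
"Fatigue","General disorders and administration site conditions"
"Drug ineffective","General disorders and administration site conditions"
"Pyrexia","General disorders and administration site conditions"
"Gait disturbance","General disorders and administration site conditions"
"Urinary tract infection","Infections and infestations"
"Pneumonia","Infections and infestations"
"Atrial fibrillation","Cardiac disorders"
"Cardiac failure","Cardiac disorders"
"Fall","Injury, poisoning and procedural complications"
"Head injury","Injury, poisoning and procedural complications"
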