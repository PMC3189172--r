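variable,set,loading
Sex (male),X,0.03
Age (<=10),X,0.94
Animal Contact,X,-0.04
Tick Bite,X,0.05
Mosquito Bite,X,0.11
Insect Bite,X,-0.08
Immunization,X,0.27
Recent Infection,X,-0.10
Travel Abroad,X,-0.06
Travel UK,X,-0.13
Raw Fish,X,-0.05
Untreated Water,X,-0.05
Water Exposure,X,0.18
Head Trauma,X,0.13
Sick Person Contact,X,0.47
Abnormal CT,Y,0.07
Abnormal MRI,Y,0.08
Abnormal EEG,Y,0.22
Abnormal Glucose,Y,-0.19
Abnormal Protein,Y,-0.39
Abnormal WCC,Y,-0.52
Lethargy,Y,0.27
Irritability,Y,0.28
PB Change,Y,-0.36
Seizure,Y,0.24
Stiff Neck,Y,-0.12
Headache,Y,-0.51
Fever,Y,-0.03
Focal-Neurological,Y,-0.06
Coma,Y,0.001
Neurological,Y,-0.24
GI Symptoms,Y,0.08
Respiratory,Y,0.13
Confusion,Y,-0.50
Rash,Y,0.11
Photophobia,Y,-0.18
Urinary,Y,-0.11
Hospital Stay (<=50d),Y,0.30
Duration (<=100d),Y,0.30
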