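"coding_system","axis","code","chapter"
"ICD-9","diagnosis","01","Infectious"
"ICD-9","diagnosis","02","Neoplasms"
"ICD-9","diagnosis","03","Endocrine"
"ICD-9","diagnosis","04","Mental"
"ICD-9","diagnosis","05","Nervous"
"ICD-9","diagnosis","06","Circulatory"
"ICD-9","diagnosis","07","Respiratory"
"ICD-9","diagnosis","08","Digestive"
"ICD-9","diagnosis","09","Genitourinary"
"ICD-9","diagnosis","10","Skin"
"ICD-9","diagnosis","11","Musculoskeletal"
"ICD-9","diagnosis","12","Injury"
"ICD-9","diagnosis","13","Symptoms"
"ICD-9","diagnosis","14","Other diagnoses"
"ICD-9","procedure","01","Medical and Surgical"
"ICD-9","procedure","02","Imaging"
"ICD-9","procedure","03","Administration"
"ICD-9","procedure","04","Extracorporeal"
"ICD-9","procedure","05","Laboratory"
"ICD-9","procedure","06","Cardiovascular procedures"
"ICD-9","procedure","07","Other procedures"
"ICD-10","diagnosis","A","Infectious"
"ICD-10","diagnosis","B","Neoplasms"
"ICD-10","diagnosis","C","Endocrine"
"ICD-10","diagnosis","D","Mental"
"ICD-10","diagnosis","E","Nervous"
"ICD-10","diagnosis","F","Circulatory"
"ICD-10","diagnosis","G","Respiratory"
"ICD-10","diagnosis","H","Digestive"
"ICD-10","diagnosis","I","Genitourinary"
"ICD-10","diagnosis","J","Skin"
"ICD-10","diagnosis","K","Musculoskeletal"
"ICD-10","diagnosis","L","Injury"
"ICD-10","diagnosis","M","Symptoms"
"ICD-10","diagnosis","N","Other diagnoses"
"ICD-10","procedure","0A","Medical and Surgical"
"ICD-10","procedure","0B","Imaging"
"ICD-10","procedure","0C","Administration"
"ICD-10","procedure","0D","Extracorporeal"
"ICD-10","procedure","0E","Laboratory"
"ICD-10","procedure","0F","Cardiovascular procedures"
"ICD-10","procedure","0G","Other procedures"
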