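sample_id,race,Race,age,dose
GSM001,Caucasian,Caucasian,45,10 mg/kg
GSM002,B,,38,10 mg/kg
GSM003,African-American,African-American,51,0
GSM004,Inuit,Inuit,NA,0
GSM005,C,C,62,10 mg/kg
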