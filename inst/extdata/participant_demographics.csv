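number,age,height_cm,weight_kg,bmi_printed
1,24,184,82,24.2
2,25,173,53,17.7
3,23,180,65,20.1
4,23,178,75,23.7
5,23,178,74,23.4
6,24,179,62,19.4
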