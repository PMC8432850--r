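patient_id,icd_code
P01,S06.5
P01,S06.74!
P01,S22.03
P02,S06.5
P02,S02.2
P03,S52.5
P03,S20.2
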