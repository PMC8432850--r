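gm_pattern	cm_target	note
S2203	S2205	GM S22.03 codes the fifth/sixth thoracic vertebra; the matching CM subcategory is S22.05
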