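label	surface_forms
metastasis	metastasis|metastases
adhesion	adhesion
migration	migration
invasion	invasion
angiogenesis	angiogenesis
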