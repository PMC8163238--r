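# surface	canonical transporter form
exosome	exosome
exosomes	exosome
exosomal	exosome
microvesicle	microvesicle
microvesicles	microvesicle
vesicle	vesicle
vesicles	vesicle
extracellular vesicle	extracellular vesicle
extracellular vesicles	extracellular vesicle
protein complex	protein complex
protein complexes	protein complex
high-density lipoprotein	high-density lipoprotein
high density lipoprotein	high-density lipoprotein
HDL	high-density lipoprotein
apoptotic body	apoptotic body
apoptotic bodies	apoptotic body
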