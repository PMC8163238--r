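# biofluid surface forms (normalized against the BTO subset when an exact
# name/synonym match exists)
serum
plasma
urine
saliva
seminal plasma
blood
cerebrospinal fluid
tears
breast milk
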