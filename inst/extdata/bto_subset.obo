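format-version: 1.2
remark: synthetic desk-scale subset of the BRENDA tissue ontology restricted to biofluids used by the fixtures

[Term]
id: BTO:0000133
name: blood serum
synonym: "serum" EXACT []

[Term]
id: BTO:0000131
name: blood plasma
synonym: "plasma" EXACT []

[Term]
id: BTO:0001419
name: urine
synonym: "urina" RELATED []

[Term]
id: BTO:0001202
name: saliva

[Term]
id: BTO:0001078
name: seminal plasma
synonym: "seminal fluid" RELATED []

[Term]
id: BTO:0000089
name: blood

[Term]
id: BTO:0000237
name: cerebrospinal fluid
synonym: "CSF" EXACT []

[Term]
id: BTO:0001367
name: tear
synonym: "tears" EXACT []
synonym: "tear fluid" EXACT []

[Term]
id: BTO:0000671
name: breast milk
synonym: "milk" BROAD []
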