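format-version: 1.2
remark: synthetic desk-scale subset of the Disease Ontology (cancer terms with MeSH xrefs for the mapping fixtures)

[Term]
id: DOID:9256
name: colorectal cancer
synonym: "colorectal carcinoma" EXACT []
xref: MESH:D015179

[Term]
id: DOID:684
name: hepatocellular carcinoma
synonym: "HCC" EXACT []
synonym: "hepatoma" RELATED []
xref: MESH:D006528

[Term]
id: DOID:10534
name: stomach cancer
synonym: "gastric cancer" EXACT []
xref: MESH:D013274

[Term]
id: DOID:1612
name: breast cancer
synonym: "breast carcinoma" EXACT []
xref: MESH:D001943

[Term]
id: DOID:3068
name: glioblastoma
synonym: "glioblastoma multiforme" EXACT []
synonym: "GBM" EXACT []
xref: MESH:D005909

[Term]
id: DOID:0060108
name: glioma
xref: MESH:D005910

[Term]
id: DOID:1324
name: lung cancer
synonym: "lung neoplasm" EXACT []
xref: MESH:D008175

[Term]
id: DOID:3908
name: non-small cell lung cancer
synonym: "NSCLC" EXACT []
xref: MESH:D002289

[Term]
id: DOID:10283
name: prostate cancer
synonym: "prostate carcinoma" EXACT []
xref: MESH:D011471

[Term]
id: DOID:1793
name: pancreatic cancer
xref: MESH:D010190

[Term]
id: DOID:2394
name: ovarian cancer
xref: MESH:D010051

[Term]
id: DOID:5520
name: head and neck squamous cell carcinoma
synonym: "HNSCC" EXACT []
xref: MESH:D000077195

[Term]
id: DOID:1909
name: melanoma
xref: MESH:D008545
xref: MESH:D008545.alt

[Term]
id: DOID:11054
name: urinary bladder cancer
synonym: "bladder cancer" EXACT []
xref: MESH:D001749

[Term]
id: DOID:4362
name: cervical cancer
xref: MESH:D002583

[Term]
id: DOID:5041
name: esophageal cancer
xref: MESH:D004938

[Term]
id: DOID:0050686
name: organ system cancer
xref: MESH:D009371
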