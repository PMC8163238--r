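format-version: 1.2
remark: synthetic desk-scale subset of the Pathway Ontology (identifiers follow the PW pattern but only the terms below are bundled)

[Term]
id: PW:0000008
name: Wnt signaling pathway
synonym: "Wnt pathway" EXACT []

[Term]
id: PW:0000605
name: phosphatidylinositol 3-kinase-Akt signaling pathway
synonym: "PI3K/AKT signaling pathway" EXACT []
synonym: "PI3K-Akt signaling pathway" EXACT []

[Term]
id: PW:0000007
name: mitogen activated protein kinase signaling pathway
synonym: "MAPK signaling pathway" EXACT []

[Term]
id: PW:0000718
name: p53 signaling pathway
synonym: "p53 pathway" EXACT []

[Term]
id: PW:0000204
name: Notch signaling pathway
synonym: "Notch pathway" EXACT []
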