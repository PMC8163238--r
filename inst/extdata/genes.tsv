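# surface	ncbi_gene_id	label (first row per id defines the label)
PTEN	5728	PTEN
phosphatase and tensin homolog	5728	PTEN
AKT1	207	AKT1
p-AKT	207	AKT1
AKT	207	AKT1
EZH2	2146	EZH2
EGFR	1956	EGFR
epidermal growth factor receptor	1956	EGFR
BMI1	648	BMI1
XIAP	331	XIAP
ROCK1	6093	ROCK1
TGF-β1	7040	TGFB1
TGF-beta1	7040	TGFB1
TGFB1	7040	TGFB1
MT1	4489	MT1
IL33	90865	IL33
IL-33	90865	IL33
MYC	4609	MYC
c-Myc	4609	MYC
BCL2	596	BCL2
Bcl-2	596	BCL2
KRAS	3845	KRAS
STAT3	6774	STAT3
VEGFA	7422	VEGFA
VEGF	7422	VEGFA
CCND1	595	CCND1
cyclin D1	595	CCND1
ZEB1	6935	ZEB1
SOX2	6657	SOX2
CDK6	1021	CDK6
NOTCH1	4851	NOTCH1
SIRT1	23411	SIRT1
PDCD4	27250	PDCD4
TIMP3	7078	TIMP3
RECK	8434	RECK
SPRY2	10253	SPRY2
PPARG	5468	PPARG
PPAR gamma	5468	PPARG
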