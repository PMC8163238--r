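# surface	doid	label (cancer-only desk-scale lexicon)
colorectal cancer	DOID:9256	colorectal cancer
colorectal carcinoma	DOID:9256	colorectal cancer
hepatocellular carcinoma	DOID:684	hepatocellular carcinoma
HCC	DOID:684	hepatocellular carcinoma
liver cancer	DOID:3571	liver cancer
stomach cancer	DOID:10534	stomach cancer
gastric cancer	DOID:10534	stomach cancer
breast cancer	DOID:1612	breast cancer
breast carcinoma	DOID:1612	breast cancer
glioblastoma	DOID:3068	glioblastoma
glioblastoma multiforme	DOID:3068	glioblastoma
GBM	DOID:3068	glioblastoma
glioma	DOID:0060108	glioma
lung cancer	DOID:1324	lung cancer
non-small cell lung cancer	DOID:3908	non-small cell lung cancer
NSCLC	DOID:3908	non-small cell lung cancer
prostate cancer	DOID:10283	prostate cancer
pancreatic cancer	DOID:1793	pancreatic cancer
ovarian cancer	DOID:2394	ovarian cancer
head and neck squamous cell carcinoma	DOID:5520	head and neck squamous cell carcinoma
HNSCC	DOID:5520	head and neck squamous cell carcinoma
melanoma	DOID:1909	melanoma
bladder cancer	DOID:11054	bladder cancer
esophageal cancer	DOID:5041	esophageal cancer
cervical cancer	DOID:4362	cervical cancer
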