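rule_id	trigger	slots	path_bound	window	tag	negation_guard
gene.reg.neg	suppress,inhibit,repress	mirna:MIRNA,gene:GENE	4	8	negative	true
gene.reg.pos	induce,increase,upregulate	mirna:MIRNA,gene:GENE	4	8	positive	true
process.assoc	associate,correlate,link	mirna:MIRNA,process:PROCESS	4	8	association	true
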