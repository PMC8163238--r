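# process terms mined from text with the cue-plus-list pattern; terms
# matching a GO/PW name or synonym are normalized to that id, the rest get
# MINED: slugs
endothelial permeability
invasion
tumor growth
cell death
drug efflux
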