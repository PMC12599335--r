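# Keyword model for mobile-genetic-element categories in locus flanks.
category	pattern
transposase	transposase|insertion sequence|IS[0-9]
integrase	integrase|site-specific recombinase|tyrosine recombinase
phage	phage|capsid|tail protein|terminase|portal|holin|endolysin
relaxase	relaxase|MobA
t4ss	VirB|type IV secretion
t4cp	TraG|type IV coupling|T4CP
conjugal	conjugal transfer|conjugation protein
defense	abortive infection|AbiV|restriction endonuclease|antiphage
amr	enterocin A immunity|bacteriocin immunity|antimicrobial resistance
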