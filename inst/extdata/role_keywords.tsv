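# Product-string vocabulary for polysaccharide locus detection and role calls.
# First matching row wins; order places specific patterns before generic ones.
# kind: which locus kind the row belongs to (cwps, eps, both).
# anchor: row may seed a locus of its kind.  eps_block: conserved proximal
# eps gene (epsRXABCD), excluded from the variable region used for eps typing.
role	kind	anchor	eps_block	pattern
transposase	both	0	0	transposase|insertion sequence|IS[0-9]
precursor_rmlA	cwps	1	0	glucose-1-phosphate thymidylyltransferase
precursor_rmlB	cwps	1	0	dTDP-glucose 4,6-dehydratase
precursor_rmlC	cwps	1	0	dTDP-4-dehydrorhamnose 3,5-epimerase
precursor_rmlD	cwps	1	0	dTDP-4-dehydrorhamnose reductase
rhamnosyltransferase	cwps	1	0	rhamnosyltransferase
regulator	eps	1	1	transcriptional regulator EpsR|EpsR$
regulator	eps	1	1	polysaccharide biosynthesis protein EpsX|EpsX$
membrane_anchor	eps	1	1	capsular polysaccharide biosynthesis protein EpsA|EpsA$
regulator	eps	1	1	tyrosine-protein kinase EpsB|capsular polysaccharide biosynthesis protein EpsB|EpsB$
regulator	eps	1	1	phosphotyrosine-protein phosphatase EpsC|capsular polysaccharide biosynthesis protein EpsC|EpsC$
regulator	eps	1	1	capsular polysaccharide biosynthesis protein EpsD|EpsD$
regulator	eps	1	0	polysaccharide biosynthesis protein EpsL|EpsL$
regulator	eps	1	0	modulator OrfY|OrfY$
priming_gt	cwps	1	0	priming glycosyltransferase WpsA|WpsA$
membrane_anchor	cwps	1	0	PSP membrane anchor|WpsB$
flippase	cwps	1	0	polysaccharide flippase WpsG|WpsG$
psp_transferase	cwps	1	0	PSP transferase WpsJ|WpsJ$
abc_transporter	both	0	0	polysaccharide ABC transporter|ABC transporter.*polysaccharide
priming_gt	both	0	0	priming glycosyltransferase|undecaprenyl-phosphate.*glycosyl.*transferase|WpsA|EpsE$
flippase	both	0	0	flippase|Wzx
copolymerase	both	0	0	co-polymerase|copolymerase|WpsH|bactoprenol glycosyltransferase
polymerase	both	0	0	polysaccharide polymerase|oligosaccharide repeat unit polymerase|Wzy|WpsI
psp_transferase	cwps	0	0	WpsJ|YcaA
modification_epimerase	both	0	0	epimerase
modification_dehydratase	both	0	0	dehydratase
modification_oxidoreductase	both	0	0	talose 4-dehydrogenase|dehydrogenase|oxidoreductase
modification_acetylase	both	0	0	O-acetylase|acetylase|acetyltransferase|OafA
modification_other	both	0	0	sulfatase|phosphotransferase|aminotransferase|pyruvyl|glycerophosphotransferase
glycosyltransferase	both	0	0	exopolysaccharide biosynthesis glycosyltransferase|glycosyltransferase|glycosyl transferase
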