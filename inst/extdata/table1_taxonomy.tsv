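taxon	blastp	tblastn
Mammalia	24	22
Aves	9	11
Amphibia	9	9
Actinopteri	21	24
Chondrichthyes	1	4
Ascidiacea	297	303
Appendicularia	1	0
Enteropneusta	2	9
Echinoidea	6	5
Insecta	4	5
Arachnida	1	1
Chromadorea	1	1
Gastropoda	9	3
Bivalvia	3	0
Hirudinida	3	3
Polychaeta	1	1
Trematoda	2	1
Anthozoa	2	3
Hydrozoa	3	1
Eurotiomycetes	1	1
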