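marker	linkage_group	cM
L001	LG1	69.867
L002	LG2	55.653
L003	LG3	14.014
L004	LG4	28.572
L005	LG5	55.537
L006	LG6	2.513
L007	LG7	46.623
L008	LG8	86.101
L009	LG9	25.25
L010	LG10	58.081
L011	LG11	0.593
L012	LG12	69.187
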