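individual	deme	group
D1_i001	D1	G1
D1_i002	D1	G1
D1_i003	D1	G1
D1_i004	D1	G1
D1_i005	D1	G1
D1_i006	D1	G1
D1_i007	D1	G1
D1_i008	D1	G1
D2_i001	D2	G1
D2_i002	D2	G1
D2_i003	D2	G1
D2_i004	D2	G1
D2_i005	D2	G1
D2_i006	D2	G1
D2_i007	D2	G1
D2_i008	D2	G1
D3_i001	D3	G1
D3_i002	D3	G1
D3_i003	D3	G1
D3_i004	D3	G1
D3_i005	D3	G1
D3_i006	D3	G1
D3_i007	D3	G1
D3_i008	D3	G1
D4_i001	D4	G2
D4_i002	D4	G2
D4_i003	D4	G2
D4_i004	D4	G2
D4_i005	D4	G2
D4_i006	D4	G2
D4_i007	D4	G2
D4_i008	D4	G2
D5_i001	D5	G2
D5_i002	D5	G2
D5_i003	D5	G2
D5_i004	D5	G2
D5_i005	D5	G2
D5_i006	D5	G2
D5_i007	D5	G2
D5_i008	D5	G2
D6_i001	D6	G2
D6_i002	D6	G2
D6_i003	D6	G2
D6_i004	D6	G2
D6_i005	D6	G2
D6_i006	D6	G2
D6_i007	D6	G2
D6_i008	D6	G2
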