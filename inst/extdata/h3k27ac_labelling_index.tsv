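sample_id	crc	normal
11028	60.9	67.1
14585	59.5	55.6
14600	55.2	54.9
14616	75.1	46.5
14882	75.7	39.2
14935	62.2	43
15244	78.5	49.3
17022	79.9	53.9
10991	89	62.4
15732	54.1	54.7
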