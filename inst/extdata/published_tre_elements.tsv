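# Published conserved thyroid response elements (mouse vs rat/human ortholog promoters).
# Long format: one row per mouse element x ortholog comparison.
# pos: TSS-relative coordinate of the element's 5'-most base (TSS = 0, negative upstream).
# printed_mm: half-site mismatch count as published; hamming_consistent = 1 where a plain
# half-site Hamming count reproduces it (one published count reflects a shifted alignment).
gene	type	mouse_pos	mouse_tre	species	pos	tre	printed_mm	hamming_consistent
H01Rik	DR4	1597	GGGTCACCAGGGGCTA	rat	1513	GGGTCACCAGGGGCTA	0	1
H01Rik	DR4	1597	GGGTCACCAGGGGCTA	human	1709	GGGTCACCAGGGGCTG	1	1
H01Rik	DR4	-5778	AGGGCAGCAGAGCTGA	rat	-5806	AGGGCAGCAGGGCTGA	1	1
H01Rik	DR4	-5778	AGGGCAGCAGAGCTGA	human	-7091	AGGGGCAGGCAGCTGA	1	0
H01Rik	DR4	-5778	AGGGCAGCAGAGCTGA	human	-4046	AGGGAAAGACAGCTCA	2	1
H01Rik	DR4	281	AGGTCAGGCGAGGGCA	rat	243	AGGTCAGGCGAGGGCA	0	1
H01Rik	DR4	281	AGGTCAGGCGAGGGCA	human	1176	TGGTCAGGCCTGGGCA	2	1
H01Rik	IR0	-2311	AGGTGAAGCCCT	rat	-2421	AGGTGAAGCCCT	0	1
H01Rik	IR0	-2311	AGGTGAAGCCCT	human	-3415	CGGTGAAACCCT	2	1
Arl4d	DR4	-2529	AGGCCAGCCAGGGCTA	rat	-1594	AGGCTAGCCTGGGCTA	1	1
Arl4d	DR4	-2529	AGGCCAGCCAGGGCTA	human	-1286	AGGCCTCAAAGGGCTT	2	1
Arl4d	DR4	-2529	AGGCCAGCCAGGGCTA	human	-922	AGGCCGATGTGGGCGA	2	1
Ces2	DR4	-5950	AGGCAAAGCAAGGTCT	rat	-7139	AGGCAACTGCAGGTTT	1	1
Ces2	DR4	-5950	AGGCAAAGCAAGGTCT	human	-7548	AGGCAAAAGCTGGGCT	2	1
Ces2	DR4	-5950	AGGCAAAGCAAGGTCT	human	-7219	TGGCAATCTGAGCTCT	2	1
Ces2	DR4	-5950	AGGCAAAGCAAGGTCT	human	-4185	AGCTAAGCCAAGGTCT	2	1
Fzd8	DR4	-143	CGGTCACCCCAGGAGA	rat	6	CGGTCACCCCAGGAGA	0	1
Fzd8	DR4	-143	CGGTCACCCCAGGAGA	human	399	CGGTCGGGCCAGGCGA	2	1
Hectd3	ER6	-7433	TGGCCTGAAGATAGGACA	rat	-6784	TGGCCTCTCCTATGGACA	1	1
Hectd3	ER6	-7433	TGGCCTGAAGATAGGACA	human	-7570	TGGCCTACAACCAGGATA	1	1
Hectd3	ER6	-7433	TGGCCTGAAGATAGGACA	human	-6806	GGGCCAATGCTCAGGACA	2	1
Hectd3	DR4	-3516	AAGTCACCTGAGGAGA	rat	-5475	AAGTCACCTGAGGAGA	0	1
Hectd3	DR4	-3516	AAGTCACCTGAGGAGA	human	-2992	AAGTCATTTGGGGAAA	2	1
Ihh	ER6	-5766	TGACCTTTATGCAAGTCA	rat	-6131	TGACCTTTATTCAAGTCA	0	1
Ihh	ER6	-5766	TGACCTTTATGCAAGTCA	human	-4898	CCACCTCTGTTCAAGTCA	2	1
Serpina9	DR4	31	AGGACAACAAGGGCGA	rat	31	AGGACAACAAAGGCGA	1	1
Serpina9	DR4	31	AGGACAACAAGGGCGA	human	167	AGGACAGGGCAGGAGA	2	1
Slc25a45	DR4	-4642	AGGATTTCTAAGGCCA	rat	-5175	AGGATTTCTATGGCCA	1	1
Slc25a45	DR4	-4642	AGGATTTCTAAGGCCA	human	-6373	AGGTTTGCAATGGCCA	2	1
Sned1	DR4	409	AGGTGGAATGAGGACA	rat	317	AGGTGGAATGAGGACA	0	1
Sned1	DR4	409	AGGTGGAATGAGGACA	human	332	AGGTGGAATGAGGACA	0	1
Sned1	DR4	409	AGGTGGAATGAGGACA	human	-864	AGGTGGGGGCAGGACT	1	1
Sned1	ER6	217	TCACCCCGAAGCAGGACG	rat	125	TCACCCCGAAGCAGGACG	0	1
Sned1	ER6	217	TCACCCCGAAGCAGGACG	human	125	TCACCCCCAAGCAGGACG	0	1
Tbcel	DR4	15	GGGTCAGCATAGGACA	rat	-7	GGGTCAATGCAGGACA	0	1
Tbcel	DR4	15	GGGTCAGCATAGGACA	human	15	GGGTCAATGCAGGACA	0	1
Tbcel	IR0	920	AGGACAAGTCCC	rat	891	AGGACAAGTCCC	0	1
Tbcel	IR0	920	AGGACAAGTCCC	human	649	AGGACATGTCCC	1	1
Tbcel	IR0	920	AGGACAAGTCCC	human	1157	GGGACAAGCCCC	2	1
Tbcel	IR0	920	AGGACAAGTCCC	human	470	GGGACCAGTCCC	2	1
Tbcel	DR4	1361	AGGCCAGCCTGGGCTA	rat	1371	AGGCCAGCCTGGGCTA	0	1
Tbcel	DR4	1361	AGGCCAGCCTGGGCTA	human	-230	AGGACAATAGGGGCTG	2	1
Tor1a	DR4	-2364	AGGACAGCCAGGGCTA	rat	-4242	AGGAAACACACGGCTA	2	1
Tor1a	DR4	-2364	AGGACAGCCAGGGCTA	human	-1610	AGGATACTCCGGGCTC	2	1
Tor1a	DR4	1648	AGGTTAGTCTGGGCTA	rat	1638	AGGTTAGTCTGGGCTG	1	1
Tor1a	DR4	1648	AGGTTAGTCTGGGCTA	human	552	CGGTTGGCTGGGGCTA	2	1
Tor1a	DR4	-2729	AGGACAGCCAGGGCTA	rat	-4242	AGGAAACACACGGCTA	2	1
Tor1a	DR4	-2729	AGGACAGCCAGGGCTA	human	-1610	AGGATACTCCGGGCTC	2	1
Tor1a	DR4	-4783	AGGCCACTTCAGGTTG	rat	-6425	AGGCCAGAAGAGGGTG	1	1
Tor1a	DR4	-4783	AGGCCACTTCAGGTTG	human	-6272	AGGCCAAGGCAGGAGG	2	1
Tor1a	DR4	-4783	AGGCCACTTCAGGTTG	human	-6628	AGGCCAGGCACGGTGG	2	1
Trim24	DR4	295	AGGACAATGGAGGTGG	rat	-5	AGGACAATGGAGGTGG	0	1
Trim24	DR4	295	AGGACAATGGAGGTGG	human	336	AGGACAATGGAGGTGG	0	1
Txnrd3	IR0	372	GGGTGATGATCT	rat	362	GGGTTATGATCT	1	1
Txnrd3	IR0	372	GGGTGATGATCT	human	1423	GGGTGGTGATCT	1	1
Txnrd3	IR0	372	GGGTGATGATCT	human	1876	GGGTGATAACCT	2	1
Klf9	DR4	-3804	AGGTGAAGTGAGGTCA	rat	-3819	AGGTGGGGCGAGGTCA	1	1
Klf9	DR4	-3804	AGGTGAAGTGAGGTCA	human	-2875	AGATTGTCTGAGGTTA	4	1
Mbp	ER6	-192	GGACCTCGGCTGAGGACA	rat	-138	GGACCTCGGCCGAGGACA	0	1
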