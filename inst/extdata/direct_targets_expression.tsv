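# Published candidate direct thyroid-hormone target genes: signed fold
# changes for the hypo, hyper and hypo+ treatment groups by sex.
# Only cells printed in the source table (i.e. significant at FDR < 0.05)
# appear as rows; fdr_p is encoded as 0.01 since the published table
# reports significance, not exact p-values. Absent cells = not significant.
gene	accession	sex	group	fold_change	fdr_p
2310003H01Rik	NM_027980	male	hyper	1.4	0.01
2310003H01Rik	NM_027980	female	hyper	1.4	0.01
2310003H01Rik	NM_027980	male	hypo_plus	1.3	0.01
4633401B06Rik	AK014609	female	hyper	1.4	0.01
4633401B06Rik	AK014609	male	hypo_plus	1.6	0.01
4633401B06Rik	AK014609	female	hypo_plus	1.7	0.01
AK044145	AK044145	male	hyper	2.6	0.01
AK044145	AK044145	female	hyper	2.7	0.01
AK044145	AK044145	male	hypo_plus	2.1	0.01
AK044145	AK044145	female	hypo_plus	1.9	0.01
Arl4d	NM_025404	male	hyper	2.0	0.01
Arl4d	NM_025404	male	hypo_plus	2.0	0.01
Auts2	NM_177047	male	hyper	3.1	0.01
Auts2	NM_177047	female	hyper	3.0	0.01
Auts2	NM_177047	male	hypo_plus	2.5	0.01
Auts2	NM_177047	female	hypo_plus	2.5	0.01
Ces2	NM_145603	male	hyper	1.5	0.01
Ces2	NM_145603	female	hyper	1.4	0.01
Ces2	NM_145603	female	hypo_plus	1.5	0.01
Ciapin1	NM_134141	male	hyper	1.4	0.01
Ciapin1	NM_134141	female	hyper	1.4	0.01
Ciapin1	NM_134141	male	hypo_plus	1.3	0.01
Coq10b	NM_026424.3	female	hyper	1.5	0.01
Coq10b	NM_026424.3	male	hypo_plus	2.0	0.01
DXBay18	NM_001025384.3	female	hypo	-1.7	0.01
DXBay18	NM_001025384.3	male	hyper	2.2	0.01
DXBay18	NM_001025384.3	female	hyper	1.7	0.01
DXBay18	NM_001025384.3	male	hypo_plus	2.6	0.01
DXBay18	NM_001025384.3	female	hypo_plus	2.3	0.01
Epm2aip1	NM_175266	male	hyper	1.3	0.01
Epm2aip1	NM_175266	female	hyper	1.3	0.01
Epm2aip1	NM_175266	male	hypo_plus	1.3	0.01
Fzd8	NM_008058	male	hyper	1.8	0.01
Fzd8	NM_008058	female	hyper	1.5	0.01
Fzd8	NM_008058	male	hypo_plus	1.6	0.01
Gramd1c	NM_153528	male	hyper	1.6	0.01
Gramd1c	NM_153528	female	hyper	1.7	0.01
Gramd1c	NM_153528	female	hypo_plus	1.4	0.01
Hectd3	NM_175244	female	hyper	1.3	0.01
Hectd3	NM_175244	female	hypo_plus	1.4	0.01
Ihh	NM_010544	female	hyper	-1.2	0.01
Ihh	NM_010544	female	hypo_plus	-1.2	0.01
Il15ra	NM_008358	female	hyper	1.2	0.01
Il15ra	NM_008358	female	hypo_plus	1.3	0.01
Lrrc8d	NM_178701	male	hyper	1.6	0.01
Lrrc8d	NM_178701	female	hyper	1.4	0.01
Lrrc8d	NM_178701	male	hypo_plus	1.6	0.01
Map3k13	NM_172821	male	hyper	1.6	0.01
Map3k13	NM_172821	male	hypo_plus	1.7	0.01
Mapk6	NM_027418	male	hyper	1.3	0.01
Mapk6	NM_027418	female	hyper	1.4	0.01
Mapk6	NM_027418	female	hypo_plus	1.3	0.01
Serpina9	NM_027997	female	hyper	-1.7	0.01
Serpina9	NM_027997	female	hypo_plus	-1.9	0.01
Sh3pxd2a	NM_008018.4	male	hyper	1.7	0.01
Sh3pxd2a	NM_008018.4	female	hyper	1.7	0.01
Sh3pxd2a	NM_008018.4	male	hypo_plus	1.5	0.01
Sh3pxd2a	NM_008018.4	female	hypo_plus	1.5	0.01
Slc25a45	NM_134154	male	hypo	-1.7	0.01
Slc25a45	NM_134154	female	hypo	-1.6	0.01
Slc25a45	NM_134154	male	hyper	1.7	0.01
Slc25a45	NM_134154	female	hyper	1.9	0.01
Slc25a45	NM_134154	male	hypo_plus	1.5	0.01
Slc25a45	NM_134154	female	hypo_plus	1.6	0.01
Sned1	NM_172463	male	hypo	-1.6	0.01
Sned1	NM_172463	female	hypo	-1.6	0.01
Sned1	NM_172463	male	hyper	1.5	0.01
Sned1	NM_172463	female	hyper	1.5	0.01
Sned1	NM_172463	male	hypo_plus	1.5	0.01
Sned1	NM_172463	female	hypo_plus	1.4	0.01
Stim2	NM_001081103	male	hyper	1.9	0.01
Stim2	NM_001081103	female	hyper	2.0	0.01
Stim2	NM_001081103	male	hypo_plus	1.5	0.01
Tbcel	NM_173038.2	male	hyper	1.3	0.01
Tbcel	NM_173038.2	female	hyper	1.3	0.01
Tbcel	NM_173038.2	male	hypo_plus	1.3	0.01
Tbcel	NM_173038.2	female	hypo_plus	1.4	0.01
Tor1a	NM_144884	female	hyper	1.2	0.01
Tor1a	NM_144884	male	hypo_plus	1.3	0.01
Trim24	NM_145076	male	hypo	-1.4	0.01
Trim24	NM_145076	female	hypo	-1.6	0.01
Trim24	NM_145076	male	hyper	1.6	0.01
Trim24	NM_145076	female	hyper	1.4	0.01
Trim24	NM_145076	male	hypo_plus	1.5	0.01
Txnrd3	NM_153162	female	hyper	1.2	0.01
Txnrd3	NM_153162	male	hypo_plus	1.3	0.01
Wipf3	XM_001481284	male	hypo	-1.4	0.01
Wipf3	XM_001481284	male	hyper	1.4	0.01
Wipf3	XM_001481284	male	hypo_plus	1.3	0.01
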