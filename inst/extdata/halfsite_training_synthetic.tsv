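# Synthetic default half-site training set: a curated stand-in for a
# literature list of validated thyroid response element half-sites.
# All hexamers are written in the AGGTCA-like scoring orientation.
# Replace with your own validated list via --training / read_training_tsv()
# for production runs; absolute bit scores depend on this file.
id	hexamer	source
hs01	AGGTCA	canonical nuclear-receptor half-site consensus
hs02	AGGTCA	canonical consensus (second occurrence, e.g. classic DR4 probes)
hs03	AGGTCA	canonical consensus (downstream half-site of Klf9 promoter element)
hs04	GGGTCA	common G1 variant seen in receptor-bound elements
hs05	AGGACA	C5>A variant, e.g. downstream half-site of the Mbp promoter element
hs06	AGGACA	C5>A variant (second occurrence)
hs07	AGGTGA	upstream half-site of the Klf9 promoter element
hs08	AGTTCA	G3>T variant found in deiodinase-type elements
hs09	AGGTAA	C5>A/T degenerate variant
hs10	AGGTCC	A6>C variant, upstream half-site of the Mbp promoter element
hs11	GGGACA	doubly substituted variant retained in bound elements
hs12	AGGCCA	T4>C variant common in natural elements
hs13	AAGTCA	G2>A variant, downstream half-site of everted elements
hs14	GGGTTA	degenerate variant rounding out positional diversity
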