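# synthetic codon-usage table (frequency per thousand); not a real genome's usage
TTT	37.7
TTC	3.5
TTA	34.9
TTG	24.4
TCT	7.2
TCC	23.8
TCA	3.2
TCG	17.4
TAT	8.9
TAC	23.7
TAA	1.3
TAG	1.3
TGT	22.3
TGC	20.7
TGA	0.7
TGG	12.3
CTT	9.8
CTC	36
CTA	4.3
CTG	37.8
CCT	29
CCC	18.9
CCA	15.5
CCG	21.2
CAT	7.6
CAC	3.9
CAA	21.3
CAG	13.2
CGT	32.8
CGC	38.9
CGA	32.8
CGG	35.1
ATT	34.2
ATC	30.8
ATA	15.4
ATG	3.3
ACT	34.8
ACC	38.1
ACA	20.5
ACG	39.9
AAT	23.9
AAC	27.5
AAA	36.5
AAG	30.3
AGT	31.2
AGC	37.3
AGA	21.9
AGG	9.6
GTT	36.5
GTC	39.4
GTA	15
GTG	33.5
GCT	9.9
GCC	4.4
GCA	26.3
GCG	18.5
GAT	21.9
GAC	13
GAA	19.9
GAG	25.5
GGT	15.3
GGC	2.9
GGA	9.3
GGG	14.9
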