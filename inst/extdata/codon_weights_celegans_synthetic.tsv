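# Synthetic C. elegans-flavoured codon relative-adaptiveness weights.
# NOT measured usage data: preferred codons follow published C. elegans
# optimal-codon assignments; alternatives decay by within-family rank
# (1, 0.62, 0.41, 0.27, 0.18, 0.12). CAI is table-relative; substitute a
# measured table to reproduce an external tool's values. Stop codons are
# listed for completeness and excluded from CAI.
codon	amino_acid	weight
TAA	*	1
TAG	*	1
TGA	*	1
GCC	A	1
GCT	A	0.62
GCA	A	0.41
GCG	A	0.27
TGC	C	1
TGT	C	0.62
GAC	D	1
GAT	D	0.62
GAG	E	1
GAA	E	0.62
TTC	F	1
TTT	F	0.62
GGA	G	1
GGT	G	0.62
GGC	G	0.41
GGG	G	0.27
CAC	H	1
CAT	H	0.62
ATC	I	1
ATT	I	0.62
ATA	I	0.41
AAG	K	1
AAA	K	0.62
CTC	L	1
CTT	L	0.62
TTG	L	0.41
CTG	L	0.27
TTA	L	0.18
CTA	L	0.12
ATG	M	1
AAC	N	1
AAT	N	0.62
CCA	P	1
CCG	P	0.62
CCT	P	0.41
CCC	P	0.27
CAA	Q	1
CAG	Q	0.62
CGC	R	1
CGT	R	0.62
AGA	R	0.41
CGA	R	0.27
CGG	R	0.18
AGG	R	0.12
TCC	S	1
TCA	S	0.62
TCT	S	0.41
TCG	S	0.27
AGC	S	0.18
AGT	S	0.12
ACC	T	1
ACA	T	0.62
ACT	T	0.41
ACG	T	0.27
GTC	V	1
GTT	V	0.62
GTG	V	0.41
GTA	V	0.27
TGG	W	1
TAC	Y	1
TAT	Y	0.62
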