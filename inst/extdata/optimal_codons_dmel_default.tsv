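amino_acid	codon	is_optimal
A	GCA	0
A	GCC	1
A	GCG	0
A	GCT	0
C	TGC	1
C	TGT	0
D	GAC	1
D	GAT	0
E	GAA	0
E	GAG	1
F	TTC	1
F	TTT	0
G	GGA	0
G	GGC	1
G	GGG	0
G	GGT	0
H	CAC	1
H	CAT	0
I	ATA	0
I	ATC	1
I	ATT	0
K	AAA	0
K	AAG	1
L	CTA	0
L	CTC	0
L	CTG	1
L	CTT	0
L	TTA	0
L	TTG	0
M	ATG	0
N	AAC	1
N	AAT	0
P	CCA	0
P	CCC	1
P	CCG	0
P	CCT	0
Q	CAA	0
Q	CAG	1
R	AGA	0
R	AGG	0
R	CGA	0
R	CGC	1
R	CGG	0
R	CGT	0
S	AGC	0
S	AGT	0
S	TCA	0
S	TCC	1
S	TCG	0
S	TCT	0
T	ACA	0
T	ACC	1
T	ACG	0
T	ACT	0
V	GTA	0
V	GTC	0
V	GTG	1
V	GTT	0
W	TGG	0
Y	TAC	1
Y	TAT	0
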