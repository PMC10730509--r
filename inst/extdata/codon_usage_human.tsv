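# Human codon usage fractions (renormalized per amino acid); columns: aa, codon, freq
aa	codon	freq
A	GCA	0.2300000000
A	GCC	0.4000000000
A	GCG	0.1100000000
A	GCT	0.2600000000
C	TGC	0.5500000000
C	TGT	0.4500000000
D	GAC	0.5400000000
D	GAT	0.4600000000
E	GAA	0.4200000000
E	GAG	0.5800000000
F	TTC	0.5500000000
F	TTT	0.4500000000
G	GGA	0.2500000000
G	GGC	0.3400000000
G	GGG	0.2500000000
G	GGT	0.1600000000
H	CAC	0.5900000000
H	CAT	0.4100000000
I	ATA	0.1600000000
I	ATC	0.4800000000
I	ATT	0.3600000000
K	AAA	0.4200000000
K	AAG	0.5800000000
L	CTA	0.0693069307
L	CTC	0.1980198020
L	CTG	0.4059405941
L	CTT	0.1287128713
L	TTA	0.0693069307
L	TTG	0.1287128713
M	ATG	1.0000000000
N	AAC	0.5400000000
N	AAT	0.4600000000
P	CCA	0.2727272727
P	CCC	0.3333333333
P	CCG	0.1111111111
P	CCT	0.2828282828
Q	CAA	0.2500000000
Q	CAG	0.7500000000
R	AGA	0.2000000000
R	AGG	0.2100000000
R	CGA	0.1100000000
R	CGC	0.1900000000
R	CGG	0.2100000000
R	CGT	0.0800000000
S	AGC	0.2400000000
S	AGT	0.1500000000
S	TCA	0.1500000000
S	TCC	0.2200000000
S	TCG	0.0600000000
S	TCT	0.1800000000
T	ACA	0.2800000000
T	ACC	0.3600000000
T	ACG	0.1200000000
T	ACT	0.2400000000
V	GTA	0.1100000000
V	GTC	0.2400000000
V	GTG	0.4700000000
V	GTT	0.1800000000
W	TGG	1.0000000000
Y	TAC	0.5700000000
Y	TAT	0.4300000000
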