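element_name	iupac_pattern	category	strand_policy
G-box	CACGTG	light	both
Box-4	ATTAAT	light	both
GT1-motif	GGTTAA	light	both
I-box	GATAAG	light	both
AE-box	AGAAACAA	light	both
TCT-motif	TCTTAC	light	both
MRE	AACCTAA	light	both
Sp1	GGGCGG	light	both
ABRE	ACGTGKC	hormone	both
CGTCA-motif	CGTCA	hormone	both
TGACG-motif	TGACG	hormone	both
TCA-element	CCATCTTTTT	hormone	both
GARE-motif	TCTGTTG	hormone	both
P-box	CCTTTTG	hormone	both
TATC-box	TATCCCA	hormone	both
AuxRR-core	GGTCCAT	hormone	both
ARE	AAACCA	stress	both
MBS	CAACTG	stress	both
LTR	CCGAAA	stress	both
TC-rich-repeats	ATTTTCTCCA	stress	both
W-box	TTGACC	stress	both
WUN-motif	AAATTTCCT	stress	both
CAT-box	GCCACT	development	both
O2-site	GATGACATGG	development	both
GCN4-motif	TGAGTCA	development	both
Skn-1-motif	GTCAT	development	both
RY-element	CATGCATG	development	both
circadian	CAAAGATATC	other	both
CCAAT-box	CAACGG	other	both
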