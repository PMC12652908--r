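# Canonical plant promoter cis-acting elements (editable convention).
# Categories: hormone, stress, light, development, core.
name	iupac	category
ABRE	ACGTG	stress
CGTCA-motif	CGTCA	hormone
TGACG-motif	TGACG	hormone
TGA-element	AACGAC	hormone
TCA-element	CCATCTTTTT	hormone
ERE	ATTTCAAA	hormone
P-box	CCTTTTG	hormone
GARE-motif	TCTGTTG	hormone
AuxRR-core	GGTCCAT	hormone
TATC-box	TATCCCA	hormone
TC-rich_repeats	ATTCTCTAAC	stress
LTR	CCGAAA	stress
MBS	CAACTG	stress
ARE	AAACCA	stress
WUN-motif	AAATTTCCT	stress
DRE-core	GCCGAC	stress
W-box	TTGACC	stress
STRE	AGGGG	stress
G-box	CACGTG	light
Box_4	ATTAAT	light
GT1-motif	GGTTAA	light
I-box	GATAAG	light
TCT-motif	TCTTAC	light
AE-box	AGAAACAA	light
MRE	AACCTAA	light
Sp1	GGGCGG	light
CAT-box	GCCACT	development
O2-site	GATGAYRTGR	development
GCN4_motif	TGAGTCA	development
RY-element	CATGCATG	development
circadian	CAANNNNATC	development
TATA-box	TATAA	core
CAAT-box	CCAAT	core
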