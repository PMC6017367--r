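element	consensus	category
Box4	ATTAAT	light
G-box	CACGTG	light
GT1-motif	GGTTAA	light
I-box	GATAAG	light
TCA-element	CCATCTTTTT	salicylic-acid
CGTCA-motif	CGTCA	MeJA
TGACG-motif	TGACG	MeJA
GARE-motif	TCTGTTG	gibberellin
P-box	CCTTTTG	gibberellin
TGA-element	AACGAC	auxin
AuxRR-core	GGTCCAT	auxin
ERE	ATTTCAAA	ethylene
ABRE	ACGTGGC	stress
TC-rich	ATTTTCTTCA	stress
ARE	AAACCA	stress
HSE	AAAAAATTTC	heat
LTR	CCGAAA	low-temperature
circadian	CAANNNNATC	circadian
CAT-box	GCCACT	meristem
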