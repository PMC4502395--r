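name	pattern	description
E-box	CANNTG	bHLH binding site (palindromic hexamer)
G-box	CACGTG	bZIP/bHLH light- and ABA-responsive element
MYB-core	CNGTTR	MYB recognition core
W-box	TTGACC	WRKY binding site
TATA-box	TATAWAW	core promoter element
CAAT-box	CCAAT	common promoter/enhancer element
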