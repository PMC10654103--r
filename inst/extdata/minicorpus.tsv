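AlphaA	p01	MKVLATEHGFDDLRKQW
AlphaA	p02	GTSEDVLKAHNPRMIY
AlphaA	p03	WNDERKATLGVSPQHM
AlphaA	p04	LLAEKGTRNDFYSWQV
AlphaB	p01	MKVLATEHGFDDLRKQW
AlphaB	p02	GTSEDVLKAHNPRMIY
AlphaB	p03	WNDERKATLGVSPQHM
AlphaB	p05	HYTRPMKEDAGNLSVW
AlphaC	p01	MKVLATEHGFDDLRKQF
AlphaC	p02	GTSEDVLKAHNPRMIY
AlphaC	p03	WNDERKATLGVSPQHM
BetaA	p10	MADEQRKLVTGHWSNYPF
BetaA	p11	KESLVRDGATMNHQWY
BetaA	p12	PVNGKELSDATRHWMQ
BetaA	p12	PVNGKELSDA
BetaB	p10	MADEQRKLVTGHWSNYPF
BetaB	p11	KESLVRDGATMNHQWY
BetaB	p12	PVNGKELSDATRHWMQ
Solo	p20	MNQRSTVAELKGHDWY
Solo	p21	FDATKGHLMNPQRSVW
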