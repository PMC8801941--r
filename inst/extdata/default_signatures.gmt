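Senescence_signature	classic CDKN-family senescence markers	Cdkn1a	Cdkn1b	Cdkn1c	Cdkn2a	Cdkn2b	Cdkn2c	Cdkn2d
Androgen_synthesis_signature	key androgen synthesis enzymes (text-named subset)	Star	Cyp11a1	Cyp17a1	Hsd3b1
mCRPs	membrane-bound complement regulatory proteins	Cd59a	Cd59b	Cd55b	Cd55	Cd46
Collagen	main collagens expressed in Leydig cells (text-named subset)	Col1a2	Col3a1	Col4a1	Col22a1
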