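sh3_id	abundance	excluded
SNX33	1	FALSE
SNX9	1	FALSE
SNX18	1	FALSE
TOCA1	1	FALSE
CIP4	1	FALSE
FBP17	1	FALSE
Tec	1	FALSE
Btk	1	FALSE
Itk	1	FALSE
Src	1	FALSE
Lyn	1	FALSE
Hck	1	FALSE
Fyn	1	FALSE
Lck	1	FALSE
Tks5(I)	1	FALSE
Tks5(V)	1	FALSE
nephrocystin	1	FALSE
NCF1(I)	1	FALSE
OSTF1	1	FALSE
AHI1	1	FALSE
RIMBP1(III)	1	FALSE
RIMBP2(III)	1	FALSE
RIMBP3(III)	1	FALSE
Eps8L1	1	FALSE
p85a	1	FALSE
ArgBP2(II)	1	FALSE
intersectin1(III)	1	FALSE
intersectin2(III)	1	FALSE
Grb2(I)	1	FALSE
Grb2(II)	1	FALSE
Nck(I)	1	FALSE
Crk(II)	0	TRUE
CrkL(II)	0	TRUE
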