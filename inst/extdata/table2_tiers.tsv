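adam_id	sh3_id	tier	previously_reported
ADAM8	SNX33	dominant	FALSE
ADAM8	TOCA1	dominant	FALSE
ADAM8	CIP4	strongly_selected	FALSE
ADAM8	SNX9	strongly_selected	FALSE
ADAM8	Tec	strongly_selected	FALSE
ADAM8	Src	strongly_selected	FALSE
ADAM8	NCF1(I)	significantly_enriched	FALSE
ADAM8	OSTF1	significantly_enriched	FALSE
ADAM9	SNX33	dominant	FALSE
ADAM9	SNX9	dominant	TRUE
ADAM9	Tec	strongly_selected	FALSE
ADAM9	SNX18	strongly_selected	FALSE
ADAM9	NCF1(I)	significantly_enriched	FALSE
ADAM9	Lyn	significantly_enriched	FALSE
ADAM9	ArgBP2(II)	significantly_enriched	FALSE
ADAM12	Src	dominant	TRUE
ADAM12	nephrocystin	dominant	FALSE
ADAM12	Lyn	strongly_selected	TRUE
ADAM12	Tks5(V)	strongly_selected	TRUE
ADAM12	Hck	strongly_selected	TRUE
ADAM12	AHI1	strongly_selected	FALSE
ADAM12	SNX33	significantly_enriched	FALSE
ADAM12	SNX9	significantly_enriched	FALSE
ADAM15	SNX33	dominant	TRUE
ADAM15	Tks5(V)	strongly_selected	TRUE
ADAM15	Src	strongly_selected	TRUE
ADAM15	SNX9	strongly_selected	TRUE
ADAM15	nephrocystin	strongly_selected	TRUE
ADAM15	Hck	strongly_selected	TRUE
ADAM15	Tec	strongly_selected	FALSE
ADAM15	Lyn	strongly_selected	TRUE
ADAM15	Tks5(I)	strongly_selected	TRUE
ADAM15	p85a	significantly_enriched	TRUE
ADAM15	Btk	significantly_enriched	FALSE
ADAM15	NCF1(I)	significantly_enriched	TRUE
ADAM15	OSTF1	significantly_enriched	FALSE
ADAM15	intersectin1(III)	significantly_enriched	FALSE
ADAM19	Tks5(I)	dominant	FALSE
ADAM19	Src	strongly_selected	FALSE
ADAM19	RIMBP1(III)	strongly_selected	FALSE
ADAM19	Eps8L1	strongly_selected	FALSE
ADAM19	NCF1(I)	strongly_selected	FALSE
ADAM19	Tec	significantly_enriched	FALSE
ADAM19	Lyn	significantly_enriched	FALSE
ADAM19	p85a	significantly_enriched	FALSE
ADAM19	nephrocystin	significantly_enriched	FALSE
ADAM19	SNX33	significantly_enriched	FALSE
ADAM19	TOCA1	significantly_enriched	FALSE
ADAM19	SNX9	significantly_enriched	TRUE
ADAM19	Tks5(V)	significantly_enriched	TRUE
ADAM19	Hck	significantly_enriched	FALSE
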