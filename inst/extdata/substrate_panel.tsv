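substrate_id	alias	sequence	protease_class	subclass	ph_opt_low	ph_opt_high	custom	derivation
DGPYSLVA-AMC	Ac-DGPYSLVA-AMC	DGPYSLVA-AMC	serine	elastase-like	7.5	8.5	TRUE	CNTN1 (791-799)
GDGPYSLVA-AMC	Ac-GDGPYSLVA-AMC	GDGPYSLVA-AMC	serine	elastase-like	7.5	8.5	TRUE	CNTN1 (790-799)
PHLVRQKR-AMC	Ac-PHLVRQKR-AMC	PHLVRQKR-AMC	serine	furin-like	6.5	8.0	TRUE	DSG2 (42-49)
KHPHLVRQKR-AMC	Ac-KHPHLVRQKR-AMC	KHPHLVRQKR-AMC	serine	furin-like	6.5	8.0	TRUE	DSG2 (40-49)
RTKR-AMC	Pyr-RTKR-AMC	RTKR-AMC	serine	furin-like	6.5	8.0	FALSE	-
RRPL-AMC	Ac-RRPL-AMC	RRPL-AMC	serine	SKI-1/S1P-like	7.5	8.0	TRUE	Multiple proteins
VFRSLK-AMC	Ac-VFRSLK-AMC	VFRSLK-AMC	serine	SKI-1/S1P-like	7.5	8.0	TRUE	PLRG1 (14-19); SKI-1/S1P (142-147)
ANQRRHLL-AMC	Ac-ANQRRHLL-AMC	ANQRRHLL-AMC	serine	SKI-1/S1P-like	7.5	8.0	TRUE	ATF6 (412-419)
ERSLK-AMC	Ac-ERSLK-AMC	ERSLK-AMC	serine	SKI-1/S1P-like	7.5	8.0	TRUE	GIIbeta (381-385); MGAM (1409-1413)
R-AMC	R-AMC	R-AMC	serine	trypsin-like	NA	NA	FALSE	-
RRHL-AMC	Ac-RRHL-AMC	RRHL-AMC	cysteine	cathepsin-like	5.0	7.0	TRUE	Multiple proteins
RRLQ-AMC	Ac-RRLQ-AMC	RRLQ-AMC	cysteine	cathepsin-like	5.0	7.0	TRUE	Multiple proteins
RSVL-AMC	Ac-RSVL-AMC	RSVL-AMC	cysteine	cathepsin-like	5.0	7.0	TRUE	Multiple proteins
PANQRRHL-AMC	Ac-PANQRRHL-AMC	PANQRRHL-AMC	cysteine	cathepsin-like	5.0	7.0	TRUE	ATF6 (411-418)
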