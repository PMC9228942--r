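name	formula	class	adducts	mz_observed	note
CAR 16:0	C23H45NO4	acylcarnitine	[M+H]+	400.3	
Cer 42:2;O	C42H81NO2	ceramide	[M+H]+	632.6	
DG O-36:4	C39H70O4	diacylglycerol	[M+H]+	603.5	
LPC 15:0	C23H48NO7P	LPC	[M-H]-	480.3	
LPC 16:0	C24H50NO7P	LPC	[M+H]+	496.3	
PC 30:0	C38H76NO8P	PC	[M+K]+	744.4	
PC 32:0	C43H82NO8P	PC	[M+K]+	772.5	mass_inconsistent
PC 32:1	C40H78NO8P	PC	[M+K]+	770.5	
PC 34:1	C42H82NO8P	PC	[M+K]+	798.5	
PC 34:3	C42H78NO8P	PC	[M+H]+	756.5	
PC 32:2 or PE 35:2	C40H76NO8P	PC	[M+H]+	730.5	
PC 33:2 or PE 36:2	C41H78NO8P	PC	[M+H]+	744.5	
PC 34:2	C42H80NO8P	PC	[M+K]+	758.5	mass_inconsistent
PC 38:3	C46H86NO8P	PC	[M+H]+	812.6	
PC 21:1	C29H56NO8P	PC	[M+H]+	578.4	
PC 25:1;O	C33H64NO9P	PC	[M+H]+	650.4	
PC O-32:2	C35H66O4	PC	[M+H]+	551.5	
PC O-42:6	C50H90NO7P	PC	[M+Na]+	870.6	
PC O-44:5	C52H96NO7P	PC	[M+Na]+	900.7	
PE 34:0	C39H78NO8P	PE	[M-H]-	718.5	
PE 36:3	C41H76NO8P	PE	[M+H]+	742.5	
PE 40:2	C45H86NO8P	PE	[M+H]+	800.5	
PE 42:7	C47H80NO8P	PE	[M+H]+	818.4	
PE O-38:6	C43H76NO7P	PE	[M+H]+	750.5	
PS O-30:2	C36H68NO9P	PS	[M+Na]+	712.4	
PS 36:1	C24H48NO9P	PS	[M-H]-	524.3	
SM 44:1;O2	C49H99N2O6P	SM	[M+K]+	881.6	
SM 41:2;O2	C46H91N2O6P	SM	[M+Na]+	821.6	
SM 43:2;O2	C48H95N2O6P	SM	[M+H]+	827.6	
SM 36:1;O2	C41H83N2O6P	SM	[M+H]+	731.6	
SM 38:1;O2	C43H87N2O6P	SM	[M+Na]+	781.5	
SM 34:2;O2	C39H77N2O6P	SM	[M+Na]+	723.5	
SM 38:0;O2	C43H89N2O6P	SM	[M+H]+	761.5	
TG 54:4	C57H102O6	TG	[M+H]+	883.7	
TG 53:2	C56H104O6	TG	[M+Na]+	895.7	
TG 52:2	C55H102O6	TG	[M+Na]+	881.7	
TG 54:3	C57H104O6	TG	[M+Na]+	907.7	
TG 56:5	C59H104O6	TG	[M+H]+	909.7	
TG 58:9	C61H100O6	TG	[M+H]+	929.7	
FA 18:2	C18H32O2	FA	[M-H]-	279.2	
FA 20:4	C20H32O2	FA	[M-H]-	303.2	
FA 22:6	C22H32O2	FA	[M-H]-	327.2	
FA 18:0	C18H36O2	FA	[M-H]-	283.2	
Glutamine	C5H10N2O3	amino acid	[M-H]-	145.0	
Glutamate	C5H9NO4	amino acid	[M-H]-	146.0	
ADP	C10H15N5O10P2	nucleotide	[M-H]-	426.0	
AMP	C10H14N5O7P	nucleotide	[M-H]-	346.0	
UMP	C9H13N2O9P	nucleotide	[M-H]-	323.0	
GMP	C10H14N5O8P	nucleotide	[M-H]-	362.0	
Xanthine	C5H4N4O2	purine	[M-H]-	151.0	
Hypoxanthine	C5H4N4O	purine	[M-H]-	135.0	
Cytidine	C9H13N3O5	nucleoside	[M-H]-	242.0	
Aspartate	C4H7NO4	amino acid	[M-H]-	132.0	
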