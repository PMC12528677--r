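name,class,formula,adducts
PC(34:1),PC,C42H82NO8P,[M+H]+;[M+Na]+;[M+K]+
PC(38:6),PC,C46H80NO8P,[M+H]+;[M+Na]+;[M+K]+
PC(40:6),PC,C48H84NO8P,[M+H]+;[M+Na]+;[M+K]+
PC(O-32:0),PC-O,C40H82NO7P,[M+H]+
PC(O-38:5),PC-O,C46H84NO7P,[M+H]+
LPC(16:0),LPC,C24H50NO7P,[M+H]+
LPC(18:0),LPC,C26H54NO7P,[M+H]+
PE(33:1),PE,C38H74NO8P,[M+H]+;[M-H]-
PE(34:2),PE,C39H74NO8P,[M+H]+;[M-H]-
PE(36:2),PE,C41H78NO8P,[M+H]+;[M-H]-
SM(34:1;O2),SM,C39H79N2O6P,[M+H]+;[M+Na]+
SM(36:1;O2),SM,C41H83N2O6P,[M+H]+
cholesterol,sterol,C27H46O,[M-H2O+H]+
TG(52:5),TG,C55H98O6,[M+H]+;[M+Na]+;[M+K]+
DG(36:2),DG,C39H72O5,[M-H2O+H]+
ACAR(18:0),ACAR,C25H49NO4,[M+H]+
PI(34:1),PI,C43H81O13P,[M+H]+;[M-H]-
PI(38:4),PI,C47H83O13P,[M+H]+;[M-H]-
PS(36:1),PS,C42H82NO10P,[M-H]-
heme B,heme,C34H32FeN4O4,[M]+.
Hoechst 33342,dye,C27H28N6O,[M]+.
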