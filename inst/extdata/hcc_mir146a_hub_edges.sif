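ELAVL1	interaction	NOVA1
ELAVL1	interaction	NRAS
ELAVL1	interaction	PARK2
ELAVL1	interaction	PTGS2
ERBB4	interaction	NOTCH2
ERBB4	interaction	NRAS
ERBB4	interaction	PTGS2
ERBB4	interaction	RAC1
ERBB4	interaction	TRAF6
HEYL	interaction	NOTCH2
IL17A	interaction	TRAF6
IQGAP1	interaction	RAC1
IRAK1	interaction	TRAF6
NOTCH2	interaction	NRAS
NOTCH2	interaction	PTGS2
NOTCH2	interaction	SMAD4
NRAS	interaction	PTGS2
NRAS	interaction	RAC1
NRAS	interaction	RACGAP1
NRAS	interaction	SMAD4
NRAS	interaction	YES1
OTUD7B	interaction	TRAF6
PARK2	interaction	RAC1
PARK2	interaction	SMAD4
PARK2	interaction	TRAF6
PTGS2	interaction	RAC1
PTPRE	interaction	YES1
RAC1	interaction	RACGAP1
RAC1	interaction	ROBO1
RAC1	interaction	SMAD4
RAC1	interaction	TRAF6
RAC1	interaction	YES1
RACGAP1	interaction	YES1
SORT1	interaction	TRAF6
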