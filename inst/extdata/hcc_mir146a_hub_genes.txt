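RAC1
NRAS
TRAF6
ERBB4
NOTCH2
PTGS2
ELAVL1
PARK2
SMAD4
YES1
RACGAP1
HEYL
IL17A
IQGAP1
IRAK1
NOVA1
OTUD7B
PTPRE
ROBO1
SORT1
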