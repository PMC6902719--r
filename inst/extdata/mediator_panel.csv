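name,precursor,pathway,unit,lod,skin,plasma
PGE2,AA,COX,pg/mg-protein,1,TRUE,TRUE
PGD2,AA,COX,pg/mg-protein,1,TRUE,TRUE
PGF2a,AA,COX,pg/mg-protein,1.5,TRUE,TRUE
TXB2,AA,COX,pg/mg-protein,1,TRUE,TRUE
6-keto-PGF1a,AA,COX,pg/mg-protein,2,TRUE,TRUE
PGJ2,AA,COX,pg/mg-protein,0.5,TRUE,FALSE
15-deoxy-PGJ2,AA,COX,pg/mg-protein,0.5,TRUE,FALSE
PGB2,AA,COX,pg/mg-protein,0.5,TRUE,FALSE
5-HETE,AA,LOX,pg/mg-protein,0.8,TRUE,TRUE
8-HETE,AA,LOX,pg/mg-protein,0.8,TRUE,TRUE
9-HETE,AA,nonenzymatic,pg/mg-protein,0.8,TRUE,FALSE
11-HETE,AA,hybrid-monohydroxy,pg/mg-protein,0.8,TRUE,TRUE
12-HETE,AA,LOX,pg/mg-protein,2,TRUE,TRUE
15-HETE,AA,hybrid-monohydroxy,pg/mg-protein,1,TRUE,TRUE
20-HETE,AA,hybrid-monohydroxy,pg/mg-protein,1,TRUE,TRUE
LTB4,AA,LOX,pg/mg-protein,0.5,TRUE,TRUE
HXA3,AA,LOX,pg/mg-protein,1,TRUE,FALSE
HXB3,AA,LOX,pg/mg-protein,1,TRUE,FALSE
5-oxo-ETE,AA,LOX,pg/mg-protein,0.8,TRUE,FALSE
15-oxo-ETE,AA,LOX,pg/mg-protein,0.8,TRUE,FALSE
5-HEPE,EPA,LOX,pg/mg-protein,0.5,TRUE,TRUE
8-HEPE,EPA,LOX,pg/mg-protein,0.5,TRUE,TRUE
9-HEPE,EPA,nonenzymatic,pg/mg-protein,0.5,TRUE,FALSE
11-HEPE,EPA,hybrid-monohydroxy,pg/mg-protein,0.5,TRUE,TRUE
12-HEPE,EPA,LOX,pg/mg-protein,0.5,TRUE,TRUE
15-HEPE,EPA,hybrid-monohydroxy,pg/mg-protein,0.5,TRUE,FALSE
18-HEPE,EPA,hybrid-monohydroxy,pg/mg-protein,0.5,TRUE,TRUE
PGE3,EPA,COX,pg/mg-protein,0.5,TRUE,TRUE
PGD3,EPA,COX,pg/mg-protein,0.5,TRUE,TRUE
TXB3,EPA,COX,pg/mg-protein,0.5,TRUE,TRUE
4-HDHA,DHA,LOX,pg/mg-protein,1,TRUE,FALSE
7-HDHA,DHA,LOX,pg/mg-protein,1,TRUE,FALSE
8-HDHA,DHA,nonenzymatic,pg/mg-protein,1,TRUE,FALSE
10-HDHA,DHA,hybrid-monohydroxy,pg/mg-protein,1,TRUE,TRUE
11-HDHA,DHA,nonenzymatic,pg/mg-protein,1,TRUE,FALSE
13-HDHA,DHA,hybrid-monohydroxy,pg/mg-protein,1,TRUE,TRUE
14-HDHA,DHA,LOX,pg/mg-protein,1,TRUE,TRUE
16-HDHA,DHA,hybrid-monohydroxy,pg/mg-protein,1,TRUE,FALSE
17-HDHA,DHA,LOX,pg/mg-protein,1,TRUE,TRUE
20-HDHA,DHA,hybrid-monohydroxy,pg/mg-protein,1,TRUE,TRUE
9-HODE,LA,hybrid-monohydroxy,pg/mg-protein,2,TRUE,TRUE
13-HODE,LA,hybrid-monohydroxy,pg/mg-protein,2,TRUE,TRUE
9-oxo-ODE,LA,nonenzymatic,pg/mg-protein,1,TRUE,FALSE
13-oxo-ODE,LA,nonenzymatic,pg/mg-protein,1,TRUE,FALSE
t-EKODE,LA,nonenzymatic,pg/mg-protein,1,TRUE,FALSE
9-HOTrE,ALA,LOX,pg/mg-protein,0.5,TRUE,TRUE
13-HOTrE,ALA,LOX,pg/mg-protein,0.5,TRUE,TRUE
8-HETrE,DGLA,LOX,pg/mg-protein,0.5,TRUE,TRUE
15-HETrE,DGLA,LOX,pg/mg-protein,0.5,TRUE,TRUE
"5,6-EET",AA,CYP450-epoxide,pg/mg-protein,1,TRUE,TRUE
"8,9-EET",AA,CYP450-epoxide,pg/mg-protein,1,TRUE,TRUE
"11,12-EET",AA,CYP450-epoxide,pg/mg-protein,1,TRUE,TRUE
"14,15-EET",AA,CYP450-epoxide,pg/mg-protein,1,TRUE,TRUE
"9,10-EpOME",LA,CYP450-epoxide,pg/mg-protein,2,TRUE,TRUE
"12,13-EpOME",LA,CYP450-epoxide,pg/mg-protein,2,TRUE,TRUE
"17,18-EpETE",EPA,CYP450-epoxide,pg/mg-protein,0.5,TRUE,TRUE
"7,8-EpDPE",DHA,CYP450-epoxide,pg/mg-protein,0.5,TRUE,FALSE
"10,11-EpDPE",DHA,CYP450-epoxide,pg/mg-protein,0.5,TRUE,TRUE
"13,14-EpDPE",DHA,CYP450-epoxide,pg/mg-protein,0.5,TRUE,TRUE
"16,17-EpDPE",DHA,CYP450-epoxide,pg/mg-protein,0.5,TRUE,TRUE
"19,20-EpDPE",DHA,CYP450-epoxide,pg/mg-protein,0.5,TRUE,TRUE
"5,6-DHET",AA,CYP450-diol,pg/mg-protein,0.5,TRUE,TRUE
"8,9-DHET",AA,CYP450-diol,pg/mg-protein,0.5,TRUE,TRUE
"11,12-DHET",AA,CYP450-diol,pg/mg-protein,0.5,TRUE,TRUE
"14,15-DHET",AA,CYP450-diol,pg/mg-protein,0.5,TRUE,TRUE
"9,10-DiHOME",LA,CYP450-diol,pg/mg-protein,1,TRUE,TRUE
"12,13-DiHOME",LA,CYP450-diol,pg/mg-protein,1,TRUE,TRUE
"8,9-DiHETE",EPA,CYP450-diol,pg/mg-protein,0.5,TRUE,TRUE
"14,15-DiHETE",EPA,CYP450-diol,pg/mg-protein,0.5,TRUE,TRUE
"17,18-DiHETE",EPA,CYP450-diol,pg/mg-protein,0.5,TRUE,TRUE
"7,8-DiHDPA",DHA,CYP450-diol,pg/mg-protein,0.5,TRUE,FALSE
"10,11-DiHDPA",DHA,CYP450-diol,pg/mg-protein,0.5,TRUE,TRUE
"16,17-DiHDPA",DHA,CYP450-diol,pg/mg-protein,0.5,TRUE,TRUE
"19,20-DiHDPA",DHA,CYP450-diol,pg/mg-protein,0.5,TRUE,TRUE
2-AG,AA,eCB,pg/mg-protein,5,TRUE,TRUE
AEA,AA,eCB,pg/mg-protein,0.5,TRUE,TRUE
PEA,SFA-MUFA,NAE,pg/mg-protein,2,TRUE,TRUE
OEA,SFA-MUFA,NAE,pg/mg-protein,2,TRUE,TRUE
SEA,SFA-MUFA,NAE,pg/mg-protein,1,TRUE,TRUE
PLEA,SFA-MUFA,NAE,pg/mg-protein,0.5,TRUE,TRUE
MEA,SFA-MUFA,NAE,pg/mg-protein,0.5,TRUE,FALSE
HPEA,SFA-MUFA,NAE,pg/mg-protein,0.5,TRUE,FALSE
PDEA,SFA-MUFA,NAE,pg/mg-protein,0.5,TRUE,FALSE
LEA,LA,NAE,pg/mg-protein,0.5,TRUE,TRUE
ALEA,ALA,NAE,pg/mg-protein,0.5,TRUE,TRUE
DGLEA,DGLA,NAE,pg/mg-protein,0.5,TRUE,TRUE
EPEA,EPA,NAE,pg/mg-protein,0.5,TRUE,TRUE
DPEA,other,NAE,pg/mg-protein,0.5,TRUE,TRUE
DHEA,DHA,NAE,pg/mg-protein,0.5,TRUE,TRUE
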