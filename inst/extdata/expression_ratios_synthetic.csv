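strain,condition,mean,sd,n
WT,25C,100,11,3
WT,39C,230,25,3
cdc25,25C,370,38,3
cdc25,39C,372,45,3
hsf1-dCTA,25C,103,12,3
hsf1-dCTA,39C,106,14,3
hsf1-dCTA cdc25,25C,228,30,3
hsf1-dCTA cdc25,39C,231,28,3
skn7,25C,98,10,3
skn7,39C,224,27,3
skn7 cdc25,25C,296,33,3
skn7 cdc25,39C,305,41,3
ras2,25C,352,40,3
ras2,39C,360,47,3
bcy1,25C,62,9,3
bcy1,39C,118,16,3
tpk1,25C,101,12,3
tpk1,39C,205,24,3
tpk2,25C,18,4,3
tpk2,39C,21,6,3
tpk3,25C,99,11,3
tpk3,39C,226,25,3
tpk1 tpk2,25C,15,4,3
tpk1 tpk2,39C,19,5,3
tpk1 tpk3,25C,104,13,3
tpk1 tpk3,39C,233,29,3
tpk2 tpk3,25C,14,4,3
tpk2 tpk3,39C,17,5,3
tpk2::TPK2 tpk3,25C,102,12,3
tpk2::TPK2 tpk3,39C,227,26,3
ssa1,25C,108,13,3
ssa1,39C,251,31,3
ssa2,25C,189,22,3
ssa2,39C,342,39,3
ssa1 ssa2,25C,478,52,3
ssa1 ssa2,39C,512,60,3
ssa1 tpk2,25C,20,5,3
ssa1 tpk2,39C,26,6,3
ssa2 tpk2,25C,23,5,3
ssa2 tpk2,39C,98,14,3
ssa1 ssa2 tpk2,25C,95,12,3
ssa1 ssa2 tpk2,39C,104,15,3
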