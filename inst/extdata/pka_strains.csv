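strain,deletions,caps
WT,,
cdc25,Cdc25,
hsf1-dCTA,,Hsf1=1
hsf1-dCTA cdc25,Cdc25,Hsf1=1
skn7,Skn7,
skn7 cdc25,Skn7;Cdc25,
ras2,Ras2,
bcy1,Bcy1,
tpk1,Tpk1,
tpk2,Tpk2,
tpk3,Tpk3,
tpk1 tpk2,Tpk1;Tpk2,
tpk1 tpk3,Tpk1;Tpk3,
tpk2 tpk3,Tpk2;Tpk3,
tpk2::TPK2 tpk3,Tpk3,
ssa1,Ssa1,
ssa2,Ssa2,
ssa1 tpk2,Ssa1;Tpk2,
ssa2 tpk2,Ssa2;Tpk2,
ssa1 ssa2,Ssa1;Ssa2,
ssa1 ssa2 tpk2,Ssa1;Ssa2;Tpk2,
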