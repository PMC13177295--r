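label,assignment,center
DNA_966,DNA,966
Glycogen_1030,Glycogen,1030
DNA_1035,DNA,1035
DNA_1082,DNA,1082
Glycogen_1154,Glycogen,1154
Proteins_1168,Proteins,1168
AmideIII_1238,Amide III,1238
AmideIII_1308,Amide III,1308
Proteins_1400,Proteins,1400
Proteins_1448,Proteins,1448
Lipids_1462,Lipids,1462
AmideII_1516,Amide II,1516
AmideII_1546,Amide II,1546
AmideI_1658,Amide I,1658
Lipids_1744,Lipids,1744
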