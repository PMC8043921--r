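"id","sex","age","histology","ct_stage","cn_stage","chemo_cycles","mandard","her2","cd44","hif1a_nucleus","hif1a_cytosol","ptch1","shh"
"P001","male",65,"adenocarcinoma","T1-2","N0-1",4,1,"negative","","","","",""
"P002","male",65,"adenocarcinoma","T1-2","N0-1",4,1,"negative","","","","",""
"P003","male",65,"adenocarcinoma","T1-2","N0-1",4,1,"negative","","","","",""
"P004","male",65,"adenocarcinoma","T1-2","N0-1",4,1,"negative","","","","",""
"P005","male",65,"adenocarcinoma","T1-2","N0-1",5,1,"negative","","","","",""
"P006","male",65,"adenocarcinoma","T1-2","N0-1",5,1,"negative","","","","",""
"P007","male",65,"adenocarcinoma","T3-4a","N0-1",5,1,"negative","","","","",""
"P008","male",65,"adenocarcinoma","T3-4a","N0-1",5,1,"negative","","","","",""
"P009","male",65,"adenocarcinoma","T3-4a","N0-1",5,1,"negative","","","","",""
"P010","male",65,"adenocarcinoma","T3-4a","N0-1",5,1,"negative","","","","",""
"P011","male",65,"adenocarcinoma","T3-4a","N0-1",5,1,"negative","","","","",""
"P012","male",65,"adenocarcinoma","T3-4a","N0-1",5,1,"negative","","","","",""
"P013","male",65,"adenocarcinoma","T3-4a","N0-1",5,1,"negative","","","","",""
"P014","male",65,"adenocarcinoma","T3-4a","N0-1",5,1,"negative","","","","",""
"P015","female",65,"adenocarcinoma","T3-4a","N0-1",5,1,"negative","","","","",""
"P016","female",65,"adenocarcinoma","T3-4a","N0-1",5,1,"negative","","","","",""
"P017","female",65,"squamous","T3-4a","N0-1",5,1,"negative","","","","",""
"P018","female",65,"squamous","T3-4a","N0-1",5,1,"negative","","","","",""
"P019","female",65,"squamous","T3-4a","N0-1",5,1,"negative","","","","",""
"P020","female",65,"squamous","T3-4a","N2-3",5,1,"positive","","","","",""
"P021","female",65,"squamous","T3-4a","N2-3",5,1,"missing","","","","",""
"P022","male",63,"adenocarcinoma","T1-2","N0-1",4,2,"negative","","","","",""
"P023","male",63,"adenocarcinoma","T1-2","N0-1",4,2,"negative","","","","",""
"P024","male",63,"adenocarcinoma","T1-2","N0-1",4,2,"negative","","","","",""
"P025","male",63,"adenocarcinoma","T1-2","N0-1",4,2,"negative","","","","",""
"P026","male",63,"adenocarcinoma","T1-2","N0-1",4,2,"negative","","","","",""
"P027","male",63,"adenocarcinoma","T3-4a","N0-1",4,2,"negative","","","","",""
"P028","male",63,"adenocarcinoma","T3-4a","N0-1",4,2,"negative","","","","",""
"P029","male",63,"adenocarcinoma","T3-4a","N0-1",4,2,"negative","","","","",""
"P030","male",63,"adenocarcinoma","T3-4a","N0-1",4,2,"negative","","","","",""
"P031","male",63,"adenocarcinoma","T3-4a","N0-1",4,2,"negative","","","","",""
"P032","male",63,"adenocarcinoma","T3-4a","N0-1",4,2,"negative","","","","",""
"P033","male",63,"adenocarcinoma","T3-4a","N0-1",4,2,"negative","","","","",""
"P034","male",63,"adenocarcinoma","T3-4a","N0-1",4,2,"negative","","","","",""
"P035","male",63,"adenocarcinoma","T3-4a","N0-1",4,2,"negative","","","","",""
"P036","male",63,"adenocarcinoma","T3-4a","N0-1",5,2,"negative","","","","",""
"P037","male",63,"adenocarcinoma","T3-4a","N0-1",5,2,"negative","","","","",""
"P038","male",63,"adenocarcinoma","T3-4a","N0-1",5,2,"negative","","","","",""
"P039","male",63,"adenocarcinoma","T3-4a","N0-1",5,2,"negative","","","","",""
"P040","male",63,"adenocarcinoma","T3-4a","N0-1",5,2,"negative","","","","",""
"P041","male",63,"adenocarcinoma","T3-4a","N0-1",5,2,"negative","","","","",""
"P042","male",63,"adenocarcinoma","T3-4a","N0-1",5,2,"negative","","","","",""
"P043","male",63,"adenocarcinoma","T3-4a","N0-1",5,2,"negative","","","","",""
"P044","male",63,"adenocarcinoma","T3-4a","N0-1",5,2,"negative","","","","",""
"P045","male",63,"adenocarcinoma","T3-4a","N0-1",5,2,"negative","","","","",""
"P046","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","","","","",""
"P047","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","","","","",""
"P048","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","","","","",""
"P049","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","","","","",""
"P050","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","","","","",""
"P051","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","","","","",""
"P052","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","","","","",""
"P053","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","","","","",""
"P054","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","","","","",""
"P055","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","","","","",""
"P056","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","","","","",""
"P057","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","","","","",""
"P058","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","","","","",""
"P059","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","","","","",""
"P060","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","","","","",""
"P061","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","","","","",""
"P062","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","","","","",""
"P063","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","","","","",""
"P064","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","","","","",""
"P065","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","","","","",""
"P066","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","","","","",""
"P067","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","","","","",""
"P068","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","","","","",""
"P069","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","","","","",""
"P070","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","","","","",""
"P071","male",63,"adenocarcinoma","T3-4a","N2-3",5,3,"negative","","","","",""
"P072","male",63,"adenocarcinoma","T3-4a","N2-3",5,3,"negative","","","","",""
"P073","male",63,"adenocarcinoma","T3-4a","N2-3",5,3,"negative","","","","",""
"P074","male",63,"adenocarcinoma","T3-4a","N2-3",5,3,"negative","","","","",""
"P075","male",63,"adenocarcinoma","T3-4a","N2-3",5,3,"negative","","","","",""
"P076","male",63,"adenocarcinoma","T3-4a","N2-3",5,3,"negative","","","","",""
"P077","male",63,"adenocarcinoma","T3-4a","N2-3",5,3,"negative","","","","",""
"P078","male",63,"adenocarcinoma","T3-4a","N2-3",5,3,"negative","","","","",""
"P079","male",63,"adenocarcinoma","T3-4a","N2-3",5,4,"positive","","","","",""
"P080","male",63,"adenocarcinoma","T3-4a","N2-3",5,4,"positive","","","","",""
"P081","male",63,"adenocarcinoma","T3-4a","N2-3",5,4,"positive","","","","",""
"P082","male",63,"adenocarcinoma","T3-4a","N2-3",5,4,"positive","","","","",""
"P083","male",63,"adenocarcinoma","T3-4a","N2-3",5,4,"positive","","","","",""
"P084","male",63,"adenocarcinoma","T3-4a","N2-3",5,4,"positive","","","","",""
"P085","male",63,"adenocarcinoma","T3-4a","N2-3",5,4,"positive","","","","",""
"P086","female",63,"adenocarcinoma","T3-4a","N2-3",5,4,"positive","","","","",""
"P087","female",63,"adenocarcinoma","T3-4a","N2-3",5,4,"positive","","","","",""
"P088","female",63,"adenocarcinoma","T3-4a","N2-3",5,4,"positive","","","","",""
"P089","female",63,"adenocarcinoma","T3-4a","N2-3",5,4,"positive","","","","",""
"P090","female",63,"adenocarcinoma","T3-4a","N2-3",5,4,"positive","","","","",""
"P091","female",63,"adenocarcinoma","T3-4a","N2-3",5,4,"positive","","","","",""
"P092","female",63,"adenocarcinoma","T3-4a","N2-3",5,4,"positive","","","","",""
"P093","female",63,"adenocarcinoma","T3-4a","N2-3",5,4,"positive","","","","",""
"P094","female",63,"squamous","T3-4a","N2-3",5,4,"positive","","","","",""
"P095","female",63,"squamous","T3-4a","N2-3",5,5,"positive","","","","",""
"P096","female",63,"squamous","T3-4a","N2-3",5,5,"missing","","","","",""
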