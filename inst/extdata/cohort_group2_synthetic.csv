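"id","sex","age","histology","ct_stage","cn_stage","chemo_cycles","mandard","her2","cd44","hif1a_nucleus","hif1a_cytosol","ptch1","shh"
"P001","male",65,"adenocarcinoma","T3-4a","N0-1",4,1,"missing","negative","negative","negative","negative","positive"
"P002","male",65,"adenocarcinoma","T1-2","N0-1",4,1,"negative","positive","negative","negative","negative","positive"
"P003","male",65,"adenocarcinoma","T1-2","N0-1",5,1,"negative","positive","negative","positive","positive","positive"
"P004","male",65,"adenocarcinoma","T1-2","N0-1",5,1,"negative","positive","negative","positive","positive","positive"
"P005","male",65,"adenocarcinoma","T3-4a","N0-1",5,1,"negative","positive","negative","positive","positive","positive"
"P006","male",65,"adenocarcinoma","T3-4a","N0-1",5,1,"negative","positive","negative","positive","positive","positive"
"P007","male",65,"adenocarcinoma","T3-4a","N0-1",5,1,"negative","positive","negative","positive","positive","positive"
"P008","female",65,"adenocarcinoma","T3-4a","N0-1",5,1,"negative","positive","negative","positive","positive","positive"
"P009","female",65,"squamous","T3-4a","N2-3",5,1,"negative","positive","positive","positive","positive","positive"
"P010","male",63,"adenocarcinoma","T1-2","N0-1",4,2,"positive","negative","negative","negative","negative","negative"
"P011","male",63,"adenocarcinoma","T3-4a","N0-1",4,2,"positive","negative","negative","negative","negative","negative"
"P012","male",63,"adenocarcinoma","T3-4a","N0-1",4,2,"negative","negative","negative","negative","negative","negative"
"P013","male",63,"adenocarcinoma","T3-4a","N0-1",4,2,"negative","negative","negative","negative","negative","positive"
"P014","male",63,"adenocarcinoma","T3-4a","N0-1",4,2,"negative","negative","negative","negative","positive","positive"
"P015","male",63,"adenocarcinoma","T3-4a","N0-1",4,2,"negative","negative","negative","negative","positive","positive"
"P016","male",63,"adenocarcinoma","T3-4a","N0-1",4,2,"negative","negative","negative","negative","positive","positive"
"P017","male",63,"adenocarcinoma","T3-4a","N0-1",4,2,"negative","negative","negative","negative","positive","positive"
"P018","male",63,"adenocarcinoma","T3-4a","N0-1",5,2,"negative","negative","negative","negative","positive","positive"
"P019","male",63,"adenocarcinoma","T3-4a","N0-1",5,2,"negative","negative","negative","negative","positive","positive"
"P020","male",63,"adenocarcinoma","T3-4a","N0-1",5,2,"negative","negative","negative","negative","positive","positive"
"P021","male",63,"adenocarcinoma","T3-4a","N0-1",5,2,"negative","negative","negative","negative","positive","positive"
"P022","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","negative","negative","negative","positive","positive"
"P023","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","negative","negative","positive","positive","positive"
"P024","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","negative","negative","positive","positive","positive"
"P025","male",63,"adenocarcinoma","T1-2","N0-1",5,3,"positive","positive","negative","positive","positive","positive"
"P026","male",63,"adenocarcinoma","T1-2","N0-1",5,3,"positive","positive","negative","positive","positive","positive"
"P027","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"positive","positive","negative","positive","positive","positive"
"P028","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"positive","positive","negative","positive","positive","positive"
"P029","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"positive","positive","negative","positive","positive","positive"
"P030","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"positive","positive","negative","positive","positive","positive"
"P031","male",63,"adenocarcinoma","T3-4a","N0-1",5,3,"negative","positive","negative","positive","positive","positive"
"P032","male",63,"adenocarcinoma","T3-4a","N2-3",5,3,"negative","positive","negative","positive","positive","positive"
"P033","male",63,"adenocarcinoma","T3-4a","N2-3",5,3,"negative","positive","negative","positive","positive","positive"
"P034","male",63,"adenocarcinoma","T3-4a","N2-3",5,3,"negative","positive","negative","positive","positive","positive"
"P035","male",63,"adenocarcinoma","T3-4a","N2-3",5,3,"negative","positive","negative","positive","positive","positive"
"P036","male",63,"adenocarcinoma","T3-4a","N2-3",5,3,"negative","positive","negative","positive","positive","positive"
"P037","male",63,"adenocarcinoma","T3-4a","N2-3",5,3,"negative","positive","negative","positive","positive","positive"
"P038","male",63,"adenocarcinoma","T3-4a","N2-3",5,3,"negative","positive","negative","positive","positive","positive"
"P039","female",63,"adenocarcinoma","T3-4a","N2-3",5,4,"negative","positive","negative","positive","positive","positive"
"P040","female",63,"adenocarcinoma","T3-4a","N2-3",5,4,"negative","positive","negative","positive","positive","positive"
"P041","female",63,"adenocarcinoma","T3-4a","N2-3",5,4,"negative","positive","positive","positive","positive","positive"
"P042","female",63,"adenocarcinoma","T3-4a","N2-3",5,4,"negative","positive","positive","positive","positive","positive"
"P043","female",63,"adenocarcinoma","T3-4a","N2-3",5,5,"negative","positive","positive","positive","positive","positive"
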