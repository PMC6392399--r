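"code","abbrev","resource_class","ownership","risk_tier"
1,"MICH-DNR",,"MICH-DNR","intermediate"
2,"PUB-WATER","water","public","high"
3,"PRI-WATER","water","private","intermediate"
4,"WAL-WATER","water","Walpole","intermediate"
5,"MICH-WATER","water","Michigan","high"
6,"PUB-MARSH","marsh","public","high"
7,"PRI-MARSH","marsh","private","intermediate"
8,"WAL-MARSH","marsh","Walpole","intermediate"
9,"CWS-MARSH","marsh","CWS","none"
10,"CWS-WATER","water","CWS","none"
11,"PRI-FLAG","flooded agriculture","private","intermediate"
12,"PRI-SUPP","supplemental feeding refuge","private","intermediate"
13,"PRI-AGRI","agriculture","private","intermediate"
14,"WAL-AGRI","agriculture","Walpole","intermediate"
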