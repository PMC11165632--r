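site,location,chloride,sulphate,nitrate,fluoride,pH
Control,Potting soil,<50,<50,<10,<10,7.5
Topaz Mountain,Utah,2440,5300,86,62,8.31
Bell Hill,Utah,890,123,38,118,9.65
Yellow Chief,Utah,185,<50,<10,<10,8.48
Minerva,Illinois,<50,752,<10,44,7.31
Hogg,Illinois,<50,<50,<10,99,7.03
Spar pile,Illinois,<50,<50,<10,48,7.05
PMT,Illinois,<50,<50,22,18,8.33
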