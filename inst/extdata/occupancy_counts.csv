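area,year,detected,monitored
Tam,2009,10,10
Tam,2010,10,10
Tam,2011,10,10
Tam,2012,8,9
SC,2008,7,9
SC,2009,8,10
SC,2010,8,10
SC,2011,9,10
SC,2012,10,10
NTL,2008,10,10
NTL,2009,10,10
NTL,2010,10,10
NTL,2011,10,10
NTL,2012,10,10
UMR,2008,1,1
UMR,2009,2,2
UMR,2010,6,6
UMR,2011,6,6
UMR,2012,6,6
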