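"genotype","environment","attribute","value"
"G1","E1","A1",2.24310157638692
"G2","E1","A1",-0.177179019947121
"G3","E1","A1",
"G4","E1","A1",-0.517464380967438
"G5","E1","A1",0.451846217602984
"G6","E1","A1",0.252938844821903
"G7","E1","A1",0.248942686930811
"G8","E1","A1",-0.243311715989474
"G1","E2","A1",-0.333517189696691
"G2","E2","A1",-2.56721682817206
"G3","E2","A1",-0.54127578356184
"G4","E2","A1",-0.939118761669133
"G5","E2","A1",-0.864032267394041
"G6","E2","A1",-1.09197423880495
"G7","E2","A1",-2.03636437258018
"G8","E2","A1",-0.119320492104974
"G1","E3","A1",
"G2","E3","A1",-1.50273669789036
"G3","E3","A1",-0.606532003119656
"G4","E3","A1",-0.82443712571952
"G5","E3","A1",-1.58325068585846
"G6","E3","A1",-0.928248291129908
"G7","E3","A1",-0.687234708986436
"G8","E3","A1",-0.346321668991762
"G1","E4","A1",1.1429924266963
"G2","E4","A1",0.299766916162949
"G3","E4","A1",0.201616706458281
"G4","E4","A1",0.689395489849618
"G5","E4","A1",1.03126491445127
"G6","E4","A1",2.26210504314811
"G7","E4","A1",0.665238128207714
"G8","E4","A1",0.82930094927818
"G1","E1","A2",0.610776550640643
"G2","E1","A2",-1.01558096030612
"G3","E1","A2",-0.665550249377599
"G4","E1","A2",0.743875257201902
"G5","E1","A2",-0.97984382563507
"G6","E1","A2",-0.451402499357057
"G7","E1","A2",-0.0693152361102302
"G8","E1","A2",
"G1","E2","A2",-0.530487879190275
"G2","E2","A2",-0.229017046826445
"G3","E2","A2",0.40630006603845
"G4","E2","A2",0.697335063570031
"G5","E2","A2",-1.06230883844624
"G6","E2","A2",-0.0217469753347209
"G7","E2","A2",-0.330740837767043
"G8","E2","A2",-1.11483533640328
"G1","E3","A2",1.39991789753447
"G2","E3","A2",0.0415437135858055
"G3","E3","A2",0.164905274738295
"G4","E3","A2",1.45369344472335
"G5","E3","A2",-0.457986978592286
"G6","E3","A2",-0.518222558263456
"G7","E3","A2",-0.572838429251275
"G8","E3","A2",-0.26181182284622
"G1","E4","A2",2.25525132272578
"G2","E4","A2",1.15515997784113
"G3","E4","A2",1.06115104972327
"G4","E4","A2",1.55138242527746
"G5","E4","A2",-0.286693992693196
"G6","E4","A2",0.0757754355762681
"G7","E4","A2",0.567559688297978
"G8","E4","A2",-0.0652917919627329
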