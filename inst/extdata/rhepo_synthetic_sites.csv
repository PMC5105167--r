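protein,site,kind,isoform_label,composition,abundance
rhEPO-synthetic,N24,N,A4S4,Hex7HexNAc6Sia4,0.0854090577803661
rhEPO-synthetic,N24,N,A4FS4,Hex7HexNAc6Fuc1Sia4,0.00255318354535468
rhEPO-synthetic,N24,N,A4S3,Hex7HexNAc6Sia3,0.286191878600538
rhEPO-synthetic,N24,N,A4FS3,Hex7HexNAc6Fuc1Sia3,0.179514319810527
rhEPO-synthetic,N24,N,A4S2,Hex7HexNAc6Sia2,0.0425096544446006
rhEPO-synthetic,N24,N,A4FS2,Hex7HexNAc6Fuc1Sia2,0.0106675267013088
rhEPO-synthetic,N24,N,A4S1,Hex7HexNAc6Sia1,0.00616119099305687
rhEPO-synthetic,N24,N,A4FS1,Hex7HexNAc6Fuc1Sia1,0.31395825593416
rhEPO-synthetic,N24,N,A4S0,Hex7HexNAc6,0.037412354227289
rhEPO-synthetic,N24,N,A4FS0,Hex7HexNAc6Fuc1,0.0356225779627983
rhEPO-synthetic,N38,N,A4S4,Hex7HexNAc6Sia4,0.279757649656115
rhEPO-synthetic,N38,N,A4FS4,Hex7HexNAc6Fuc1Sia4,0.106656309875391
rhEPO-synthetic,N38,N,A4S3,Hex7HexNAc6Sia3,0.170556327747665
rhEPO-synthetic,N38,N,A4FS3,Hex7HexNAc6Fuc1Sia3,0.0363927799726456
rhEPO-synthetic,N38,N,A4S2,Hex7HexNAc6Sia2,0.0476393997627841
rhEPO-synthetic,N38,N,A4FS2,Hex7HexNAc6Fuc1Sia2,0.180019276545151
rhEPO-synthetic,N38,N,A4S1,Hex7HexNAc6Sia1,0.109114291902885
rhEPO-synthetic,N38,N,A4FS1,Hex7HexNAc6Fuc1Sia1,0.00738828797895156
rhEPO-synthetic,N38,N,A4S0,Hex7HexNAc6,0.062475676558412
rhEPO-synthetic,N83,N,A4S4,Hex7HexNAc6Sia4,0.137706041775257
rhEPO-synthetic,N83,N,A4FS4,Hex7HexNAc6Fuc1Sia4,0.179097247689049
rhEPO-synthetic,N83,N,A4S3,Hex7HexNAc6Sia3,0.19286642415399
rhEPO-synthetic,N83,N,A4FS3,Hex7HexNAc6Fuc1Sia3,0.221626480225608
rhEPO-synthetic,N83,N,A4S2,Hex7HexNAc6Sia2,0.156209780789291
rhEPO-synthetic,N83,N,A4FS2,Hex7HexNAc6Fuc1Sia2,0.00744579454942668
rhEPO-synthetic,N83,N,A4S1,Hex7HexNAc6Sia1,0.0856516040272385
rhEPO-synthetic,N83,N,A4FS1,Hex7HexNAc6Fuc1Sia1,0.0193966267901391
rhEPO-synthetic,S126,O,unoccupied,,0.0999020236346662
rhEPO-synthetic,S126,O,core1S0,Hex1HexNAc1,0.00523032798466521
rhEPO-synthetic,S126,O,core1S1,Hex1HexNAc1Sia1,0.842994640629971
rhEPO-synthetic,S126,O,core1S2,Hex1HexNAc1Sia2,0.0518730077506973
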