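sample_id	group	target_id	replicate	ct
control_s1	control	RNU1A	1	19.7193720552187
control_s1	control	RNU1A	2	19.7661847742614
control_s1	control	RNU1A	3	19.7614184451071
control_s1	control	miR-199a-3p	1	26.558201780797
control_s1	control	miR-199a-3p	2	26.5171112225574
control_s1	control	miR-199a-3p	3	26.4534897534224
control_s1	control	miR-214-3p	1	25.3718397691161
control_s1	control	miR-214-3p	2	25.402356643661
control_s1	control	miR-214-3p	3	25.5495850300067
control_s1	control	let-7g	1	27.9202650300238
control_s1	control	let-7g	2	27.7845234361037
control_s1	control	let-7g	3	27.9509640013666
control_s1	control	miR-15b-5p	1	27.7256897259405
control_s1	control	miR-15b-5p	2	27.7419150593785
control_s1	control	miR-15b-5p	3	27.7985638577192
control_s2	control	RNU1A	1	19.8418946644644
control_s2	control	RNU1A	2	19.7417513910985
control_s2	control	RNU1A	3	19.9696578061219
control_s2	control	miR-199a-3p	1	26.1236424253115
control_s2	control	miR-199a-3p	2	26.3478025444689
control_s2	control	miR-199a-3p	3	26.4515753851534
control_s2	control	miR-214-3p	1	25.702023707625
control_s2	control	miR-214-3p	2	25.991480152439
control_s2	control	miR-214-3p	3	25.9270738407594
control_s2	control	let-7g	1	27.1277605618481
control_s2	control	let-7g	2	26.9770462171243
control_s2	control	let-7g	3	27.2765937307107
control_s2	control	miR-15b-5p	1	27.8478372195238
control_s2	control	miR-15b-5p	2	27.8252794065751
control_s2	control	miR-15b-5p	3	27.9231308508047
control_s3	control	RNU1A	1	19.5623395326869
control_s3	control	RNU1A	2	19.8332146677611
control_s3	control	RNU1A	3	19.6428630473355
control_s3	control	miR-199a-3p	1	26.2320474358637
control_s3	control	miR-199a-3p	2	26.1999937852234
control_s3	control	miR-199a-3p	3	26.395201425407
control_s3	control	miR-214-3p	1	25.5008508565768
control_s3	control	miR-214-3p	2	25.6924332578588
control_s3	control	miR-214-3p	3	25.492363451183
control_s3	control	let-7g	1	27.1922651940513
control_s3	control	let-7g	2	26.9315943322237
control_s3	control	let-7g	3	27.0871153677372
control_s3	control	miR-15b-5p	1	27.8527905836693
control_s3	control	miR-15b-5p	2	27.8265692388024
control_s3	control	miR-15b-5p	3	27.9121289673497
control_s4	control	RNU1A	1	19.061843957443
control_s4	control	RNU1A	2	18.9775564482272
control_s4	control	RNU1A	3	19.2377819168247
control_s4	control	miR-199a-3p	1	25.1530664605802
control_s4	control	miR-199a-3p	2	25.1838352755673
control_s4	control	miR-199a-3p	3	25.2437222301885
control_s4	control	miR-214-3p	1	25.2645539018412
control_s4	control	miR-214-3p	2	25.2508989138679
control_s4	control	miR-214-3p	3	25.1412547587823
control_s4	control	let-7g	1	26.3091690865831
control_s4	control	let-7g	2	26.3967784159823
control_s4	control	let-7g	3	26.4415654401351
control_s4	control	miR-15b-5p	1	26.4997031967051
control_s4	control	miR-15b-5p	2	26.4340544838876
control_s4	control	miR-15b-5p	3	26.6267345457581
control_s5	control	RNU1A	1	19.4402480490103
control_s5	control	RNU1A	2	19.3842396900296
control_s5	control	RNU1A	3	19.33501739233
control_s5	control	miR-199a-3p	1	25.9771595050797
control_s5	control	miR-199a-3p	2	25.9764665096195
control_s5	control	miR-199a-3p	3	26.2219353467183
control_s5	control	miR-214-3p	1	25.4951294527933
control_s5	control	miR-214-3p	2	25.8838221154836
control_s5	control	miR-214-3p	3	25.8409005544392
control_s5	control	let-7g	1	27.1868802643987
control_s5	control	let-7g	2	27.1543035617331
control_s5	control	let-7g	3	27.198685048159
control_s5	control	miR-15b-5p	1	26.9606792541839
control_s5	control	miR-15b-5p	2	26.9178727496681
control_s5	control	miR-15b-5p	3	26.8473028683315
EtOH_s1	EtOH	RNU1A	1	20.2995544221832
EtOH_s1	EtOH	RNU1A	2	20.3642700262384
EtOH_s1	EtOH	RNU1A	3	20.2247632919647
EtOH_s1	EtOH	miR-199a-3p	1	25.8288732807708
EtOH_s1	EtOH	miR-199a-3p	2	25.5774045141387
EtOH_s1	EtOH	miR-199a-3p	3	25.6843680317251
EtOH_s1	EtOH	miR-214-3p	1	25.6335078318559
EtOH_s1	EtOH	miR-214-3p	2	25.7536292952863
EtOH_s1	EtOH	miR-214-3p	3	25.8230803176249
EtOH_s1	EtOH	let-7g	1	26.9095877369719
EtOH_s1	EtOH	let-7g	2	26.8674078523925
EtOH_s1	EtOH	let-7g	3	26.8436063964945
EtOH_s1	EtOH	miR-15b-5p	1	29.2726010329005
EtOH_s1	EtOH	miR-15b-5p	2	29.4418066148767
EtOH_s1	EtOH	miR-15b-5p	3	29.3063681850896
EtOH_s2	EtOH	RNU1A	1	19.4313153314309
EtOH_s2	EtOH	RNU1A	2	19.3445554724831
EtOH_s2	EtOH	RNU1A	3	19.6396689776588
EtOH_s2	EtOH	miR-199a-3p	1	24.0586625971848
EtOH_s2	EtOH	miR-199a-3p	2	24.1277486014595
EtOH_s2	EtOH	miR-199a-3p	3	23.9871086561069
EtOH_s2	EtOH	miR-214-3p	1	24.7990214763526
EtOH_s2	EtOH	miR-214-3p	2	24.7168686652651
EtOH_s2	EtOH	miR-214-3p	3	24.7845382016243
EtOH_s2	EtOH	let-7g	1	25.6875336504428
EtOH_s2	EtOH	let-7g	2	25.6499341518587
EtOH_s2	EtOH	let-7g	3	25.610115887805
EtOH_s2	EtOH	miR-15b-5p	1	28.0760577093372
EtOH_s2	EtOH	miR-15b-5p	2	27.8901423913237
EtOH_s2	EtOH	miR-15b-5p	3	27.8743294821761
EtOH_s3	EtOH	RNU1A	1	20.7105218729209
EtOH_s3	EtOH	RNU1A	2	20.7499019288585
EtOH_s3	EtOH	RNU1A	3	20.6380042527416
EtOH_s3	EtOH	miR-199a-3p	1	26.2547449378317
EtOH_s3	EtOH	miR-199a-3p	2	26.3449271228542
EtOH_s3	EtOH	miR-199a-3p	3	26.3126944225833
EtOH_s3	EtOH	miR-214-3p	1	25.6458655107992
EtOH_s3	EtOH	miR-214-3p	2	25.6064143168365
EtOH_s3	EtOH	miR-214-3p	3	25.7668399879785
EtOH_s3	EtOH	let-7g	1	27.0345376861166
EtOH_s3	EtOH	let-7g	2	26.9716676091015
EtOH_s3	EtOH	let-7g	3	26.8193006916006
EtOH_s3	EtOH	miR-15b-5p	1	29.5514182081424
EtOH_s3	EtOH	miR-15b-5p	2	29.5427295292782
EtOH_s3	EtOH	miR-15b-5p	3	29.5176118261374
EtOH_s4	EtOH	RNU1A	1	20.315464079334
EtOH_s4	EtOH	RNU1A	2	20.394573059152
EtOH_s4	EtOH	RNU1A	3	20.5007702603252
EtOH_s4	EtOH	miR-199a-3p	1	25.5488534985485
EtOH_s4	EtOH	miR-199a-3p	2	25.5330901340911
EtOH_s4	EtOH	miR-199a-3p	3	25.542533707899
EtOH_s4	EtOH	miR-214-3p	1	25.5324808660064
EtOH_s4	EtOH	miR-214-3p	2	25.2638457560864
EtOH_s4	EtOH	miR-214-3p	3	25.2204751581046
EtOH_s4	EtOH	let-7g	1	26.5619129931031
EtOH_s4	EtOH	let-7g	2	26.5185541541156
EtOH_s4	EtOH	let-7g	3	26.6378506844974
EtOH_s4	EtOH	miR-15b-5p	1	29.3739399711465
EtOH_s4	EtOH	miR-15b-5p	2	29.5260348139085
EtOH_s4	EtOH	miR-15b-5p	3	29.5519285636862
EtOH_s5	EtOH	RNU1A	1	19.8674710618923
EtOH_s5	EtOH	RNU1A	2	19.8566318099518
EtOH_s5	EtOH	RNU1A	3	19.7673281056498
EtOH_s5	EtOH	miR-199a-3p	1	25.6885312535407
EtOH_s5	EtOH	miR-199a-3p	2	25.9115735743206
EtOH_s5	EtOH	miR-199a-3p	3	26.0144113591896
EtOH_s5	EtOH	miR-214-3p	1	25.5006412731385
EtOH_s5	EtOH	miR-214-3p	2	25.4207855040246
EtOH_s5	EtOH	miR-214-3p	3	25.2424947405447
EtOH_s5	EtOH	let-7g	1	26.1541200252588
EtOH_s5	EtOH	let-7g	2	26.2913623821045
EtOH_s5	EtOH	let-7g	3	26.4620419133064
EtOH_s5	EtOH	miR-15b-5p	1	29.2624582608517
EtOH_s5	EtOH	miR-15b-5p	2	29.0693982350656
EtOH_s5	EtOH	miR-15b-5p	3	29.4233914691314
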