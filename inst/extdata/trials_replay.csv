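"group","outcome","depth_um","excitation_s"
"RoseBengal","BLOCKAGE",100,840.363996113575
"RoseBengal","BLOCKAGE",200,291.170999385037
"RoseBengal","BLOCKAGE",100,455.191356551425
"RoseBengal","BLOCKAGE",150,306.30048572565
"RoseBengal","BLOCKAGE",100,132.763528001459
"RoseBengal","BLOCKAGE",200,342.478267390727
"RoseBengal","BLOCKAGE",200,58.0817332614718
"RoseBengal","BLOCKAGE",150,629.749843851649
"RoseBengal","BLOCKAGE",150,334.482001097677
"RoseBengal","BLOCKAGE",200,788.837625831484
"RoseBengal","BLOCKAGE",200,406.989644002424
"RoseBengal","BLOCKAGE",100,140.262053042592
"RoseBengal","BLOCKAGE",100,437.413429535037
"RoseBengal","BLOCKAGE",100,89.8280328800434
"RoseBengal","BLOCKAGE",150,17.932484946202
"RoseBengal","BLOCKAGE",150,365.575402991429
"RoseBengal","BLOCKAGE",150,200.259328525853
"RoseBengal","BLOCKAGE",150,300.248704117115
"RoseBengal","BLOCKAGE",200,316.726797934124
"RoseBengal","BLOCKAGE",100,167.357787107684
"RoseBengal","BLOCKAGE",200,172.049535115837
"RoseBengal","BLOCKAGE",100,269.584811597138
"RoseBengal","BLOCKAGE",100,565.069574228971
"RoseBengal","BLOCKAGE",100,525.006480835631
"RoseBengal","BLOCKAGE",100,433.637892216395
"RoseBengal","BLOCKAGE",150,374.913833523042
"RoseBengal","BLOCKAGE",100,539.197463387182
"RoseBengal","BLOCKAGE",100,231.558617182282
"RoseBengal","BLOCKAGE",150,383.254232231165
"RoseBengal","BLOCKAGE",150,360.097227923752
"RoseBengal","BLOCKAGE",150,177.932993026879
"RoseBengal","BLOCKAGE",100,571.770256346214
"RoseBengal","BLOCKAGE",200,561.090588531364
"RoseBengal","BLOCKAGE",100,457.548071140875
"RoseBengal","BLOCKAGE",200,657.03752727169
"RoseBengal","BLOCKAGE",150,425.659445752193
"RoseBengal","BLOCKAGE",150,12.7667530969418
"RoseBengal","BLOCKAGE",150,171.015281796701
"RoseBengal","BLOCKAGE",150,24.4621616478699
"RoseBengal","BLOCKAGE",200,193.484856801155
"RoseBengal","BLOCKAGE",150,160.417497624572
"RoseBengal","BLOCKAGE",100,309.476071457453
"RoseBengal","BLOCKAGE",200,95.0426290756998
"RoseBengal","BLOCKAGE",150,335.556473790917
"RoseBengal","BLOCKAGE",100,152.718455118266
"RoseBengal","BLOCKAGE",100,697.639635608845
"RoseBengal","BLOCKAGE",200,461.259182103871
"RoseBengal","BLOCKAGE",150,504.789201636426
"RoseBengal","BLOCKAGE",150,386.441705510928
"RoseBengal","BLOCKAGE",200,678.489618116869
"RoseBengal","BLOCKAGE",200,156.95929786148
"RoseBengal","BLOCKAGE",150,196.129935668873
"RoseBengal","BLOCKAGE",150,622.263503671874
"RoseBengal","BLOCKAGE",150,153.593320505167
"RoseBengal","BLOCKAGE",150,253.339332689558
"RoseBengal","BLOCKAGE",100,211.618215875554
"RoseBengal","BLOCKAGE",150,228.001604576586
"RoseBengal","HEMORRHAGE",150,237.199506830274
"RoseBengal","HEMORRHAGE",150,411.192374535261
"RoseBengal","HEMORRHAGE",150,260.100641489339
"RoseBengal","HEMORRHAGE",100,186.159571024292
"RoseBengal","HEMORRHAGE",200,602.183735663343
"RoseBengal","HEMORRHAGE",200,251.719633076955
"RoseBengal","HEMORRHAGE",150,259.599780740238
"RoseBengal","HEMORRHAGE",200,277.457083226949
"RoseBengal","HEMORRHAGE",200,460.349919086566
"RoseBengal","NONE",150,283.448009071577
"RoseBengal","NONE",200,291.532311419914
"RoseBengal","NONE",200,146.626392279977
"RoseBengal","NONE",100,227.039188744578
"RoseBengal","NONE",100,313.536099097766
"RoseBengal","NONE",100,167.498740591576
"RoseBengal","NONE",100,419.586643342329
"RoseBengal","NONE",200,160.214993670715
"RoseBengal","NONE",150,368.975518677697
"RoseBengal","NONE",200,499.445096559361
"RoseBengal","NONE",100,232.280371461763
"RoseBengal","NONE",100,181.137021499874
"RoseBengal","NONE",150,153.278674346775
"RoseBengal","NONE",100,287.198224984337
"RoseBengal","NONE",100,720.590390045306
"RoseBengal","NONE",100,564.731245204177
"RoseBengal","NONE",100,395.647584908801
"RoseBengal","NONE",200,195.705659668713
"RoseBengal","NONE",150,48.9179763653598
"RoseBengal","NONE",100,131.065724731474
"RoseBengal","NONE",100,769.612472766378
"RoseBengal","NONE",200,303.914014430982
"RoseBengal","NONE",200,10.5823806522768
"RoseBengal","NONE",200,246.304402294568
"RoseBengal","NONE",150,401.292097786347
"RoseBengal","NONE",150,295.824037639206
"RoseBengal","NONE",150,228.434615727635
"RoseBengal","NONE",200,90.893516822917
"RoseBengal","NONE",150,538.15868595953
"FitC","BLOCKAGE",100,18.0098049882695
"FitC","BLOCKAGE",200,444.50429377751
"FitC","BLOCKAGE",150,289.940444198855
"FitC","BLOCKAGE",100,231.191530552432
"FitC","BLOCKAGE",150,300.479668428061
"FitC","BLOCKAGE",200,158.182424866167
"FitC","BLOCKAGE",100,223.282069531409
"FitC","BLOCKAGE",150,39.771218406933
"FitC","BLOCKAGE",150,705.70692928143
"FitC","BLOCKAGE",150,225.495291811975
"FitC","BLOCKAGE",100,501.07658304574
"FitC","BLOCKAGE",100,344.368523716383
"FitC","HEMORRHAGE",100,359.214520441232
"FitC","HEMORRHAGE",100,78.1889924079096
"FitC","HEMORRHAGE",150,64.3579164612085
"FitC","HEMORRHAGE",100,155.891616922849
"FitC","HEMORRHAGE",100,428.364218082109
"FitC","HEMORRHAGE",200,286.562262890413
"FitC","HEMORRHAGE",150,277.909782598822
"FitC","HEMORRHAGE",200,426.184663939526
"FitC","NONE",100,33.0468063196184
"FitC","NONE",200,546.774834961705
"FitC","NONE",150,298.797593637413
"FitC","NONE",100,459.144900164568
"FitC","NONE",100,532.674240315929
"FitC","NONE",150,350.283093355943
"FitC","NONE",200,102.290787105146
"FitC","NONE",200,561.667025092649
"FitC","NONE",200,743.550911900434
"FitC","NONE",200,177.422083499612
"FitC","NONE",150,242.474090439678
"FitC","NONE",100,262.622766727874
"FitC","NONE",150,529.604379476424
"FitC","NONE",100,330.649925948125
"FitC","NONE",100,391.612710770363
"FitC","NONE",200,284.327667072096
"FitC","NONE",150,244.275523135651
"FitC","NONE",200,456.498931489419
"FitC","NONE",200,557.901380373555
"FitC","NONE",200,213.682776085119
"FitC","NONE",150,428.866399930314
"FitC","NONE",150,384.312991525197
"FitC","NONE",100,204.314762649883
"FitC","NONE",200,513.977881704784
"FitC","NONE",200,212.421634113365
"FitC","NONE",100,236.025601095096
"FitC","NONE",150,492.917200067956
"FitC","NONE",100,686.916142302135
"FitC","NONE",200,360.762352710876
"FitC","NONE",200,205.008597797781
"FitC","NONE",100,32.4495086565934
"FitC","NONE",100,225.517579752223
"FitC","NONE",150,88.5384015352452
"FitC","NONE",100,241.740168798273
"FitC","NONE",100,388.735312849854
"FitC","NONE",200,108.332154294631
"FitC","NONE",150,896.062548246348
"FitC","NONE",200,335.102627024643
"FitC","NONE",100,554.296635177362
"FitC","NONE",200,672.182693011873
"FitC","NONE",100,466.725260368974
"FitC","NONE",200,3.84483889839862
"FitC","NONE",200,506.955827462057
"FitC","NONE",150,389.57928497669
"FitC","NONE",100,208.306069664301
"FitC","NONE",150,597.958191789886
"FitC","NONE",100,142.222874419443
"FitC","NONE",100,169.361781545879
"FitC","NONE",200,74.7587592692808
"FitC","NONE",150,149.659813480486
"FitC","NONE",150,512.666614508944
"FitC","NONE",200,397.582983647661
"FitC","NONE",100,526.160823977335
"FitC","NONE",100,212.223300587922
"FitC","NONE",200,384.683315649296
"FitC","NONE",150,354.937108009461
"FitC","NONE",100,640.247856138892
"FitC","NONE",200,700.146589681976
"FitC","NONE",200,330.250723710077
"FitC","NONE",100,472.259774810519
"FitC","NONE",200,514.905752304521
"FitC","NONE",150,288.622717175489
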