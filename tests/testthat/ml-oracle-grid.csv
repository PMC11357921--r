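alpha,z,value
0.1,0.0,1.0
0.1,-0.5,0.65432446028800193
0.1,-1.0,0.4855644643110821
0.1,-1.5,0.38582613336378369
0.1,-2.0,0.3200153359597274
0.1,-2.5,0.27335667076010758
0.1,-3.0,0.23855934978253856
0.1,-3.5,0.21161383631179027
0.1,-4.0,0.19013365426129279
0.1,-4.5,0.17260999366306696
0.1,-5.0,0.15804238235845183
0.2,0.0,1.0
0.2,-0.5,0.64296499192613901
0.2,-1.0,0.47110068893348295
0.2,-1.5,0.37097697838398594
0.2,-2.0,0.30567869641870601
0.2,-2.5,0.25981009337060623
0.2,-3.0,0.2258545451264881
0.2,-3.5,0.19971876935981548
0.2,-4.0,0.17898748455870155
0.2,-4.5,0.1621451580569823
0.2,-5.0,0.1481934412461192
0.3,0.0,1.0
0.3,-0.5,0.63264900594359902
0.3,-1.0,0.45659440832969067
0.3,-1.5,0.35538165657360314
0.3,-2.0,0.29023222616787535
0.3,-2.5,0.24498312379478694
0.3,-3.0,0.21180263319643578
0.3,-3.5,0.18646550952401198
0.3,-4.0,0.16650174431551665
0.3,-4.5,0.15037490568877673
0.3,-5.0,0.13708086902027064
0.4,0.0,1.0
0.4,-0.5,0.62349640387529039
0.4,-1.0,0.44206335968522351
0.4,-1.5,0.33894977293687496
0.4,-2.0,0.27353529996067954
0.4,-2.5,0.22872353036332394
0.4,-3.0,0.19625892833053849
0.4,-3.5,0.17172487449879334
0.4,-4.0,0.15256509446300082
0.4,-4.5,0.13720546311345891
0.4,-5.0,0.12462707110373716
0.5,0.0,1.0
0.5,-0.5,0.61569034419292587
0.5,-1.0,0.427583576155807
0.5,-1.5,0.3215854164543175
0.5,-2.0,0.25539567631050574
0.5,-2.5,0.21080636406114358
0.5,-3.0,0.17900115118138995
0.5,-3.5,0.1552936556088943
0.5,-4.0,0.13699945762506139
0.5,-4.5,0.12248480427384142
0.5,-5.0,0.11070463773306863
0.6,0.0,1.0
0.6,-0.5,0.60947582195620002
0.6,-1.0,0.4133273409431063
0.6,-1.5,0.3032148361988204
0.6,-2.0,0.23557103111182496
0.6,-2.5,0.19091670740116979
0.6,-3.0,0.15970348026509122
0.6,-3.5,0.13686687334737736
0.6,-4.0,0.11953416195706788
0.6,-4.5,0.10598026464026231
0.6,-5.0,0.095117846438754617
0.7,0.0,1.0
0.7,-0.5,0.60514759205956427
0.7,-1.0,0.39961197811559938
0.7,-1.5,0.28384096962173716
0.7,-2.0,0.21378672701529727
0.7,-2.5,0.16863128667619574
0.7,-3.0,0.13789710966502707
0.7,-3.5,0.11599093758675772
0.7,-4.0,0.099760254890514619
0.7,-4.5,0.087338271657445577
0.7,-5.0,0.077569357764769802
0.8,0.0,1.0
0.8,-0.5,0.6030237158628037
0.8,-1.0,0.38694857861897685
0.8,-1.5,0.26363903543962694
0.8,-2.0,0.18979669236370566
0.8,-2.5,0.14341738258439234
0.8,-3.0,0.1129201986822174
0.8,-3.5,0.091988074514627075
0.8,-4.0,0.07704867993034476
0.8,-4.5,0.066008143964124827
0.8,-5.0,0.057595384762152254
0.9,0.0,1.0
0.9,-0.5,0.60340549869586097
0.9,-1.0,0.37606602142464188
0.9,-1.5,0.24309267847921726
0.9,-2.0,0.16352830001693005
0.9,-2.5,0.11469986754557785
0.9,-3.0,0.083888354033773269
0.9,-3.5,0.063854273735752437
0.9,-4.0,0.050411103314434623
0.9,-4.5,0.041095646312693476
0.9,-5.0,0.034431324804098424
1.0,0.0,1.0
1.0,-0.5,0.60653065971263342
1.0,-1.0,0.36787944117144232
1.0,-1.5,0.22313016014842983
1.0,-2.0,0.13533528323661269
1.0,-2.5,0.082084998623898795
1.0,-3.0,0.049787068367863943
1.0,-3.5,0.030197383422318501
1.0,-4.0,0.01831563888873418
1.0,-4.5,0.011108996538242306
1.0,-5.0,0.0067379469990854671
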