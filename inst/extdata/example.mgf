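BEGIN IONS
TITLE=sim_0001
PEPMASS=466.235242
CHARGE=2+
SEQ=QSNATKWP
90.370483 0.9344
94.018970 174.8717
98.609210 3.9874
116.066216 806.2151
117.083431 200.7834
119.730427 32.2848
129.065857 397.1706
130.067794 195.8108
156.561478 52.2503
167.759832 4.4809
209.007509 47.2717
216.097288 414.2629
217.088388 203.4951
220.003035 51.5151
237.785691 49.7018
272.265705 32.5919
279.232534 178.5863
286.482505 119.1813
302.151332 1108.3422
309.115058 37.8120
313.138260 719.4308
330.154810 2033.6937
331.164416 1022.8089
363.890454 13.1525
382.939326 133.0380
384.122468 28.4042
396.567724 31.0291
399.661366 36.0766
401.164541 212.7083
402.169221 49.3640
412.238194 225.4759
413.232641 216.7174
430.245247 727.2296
431.262939 358.8782
450.689406 46.3790
466.179495 106.2975
502.216391 270.1434
531.291999 632.8374
532.444281 161.7637
554.072881 7.0628
585.304133 123.3097
594.618171 42.6884
602.329055 403.2701
603.338866 220.2439
630.325459 687.8997
631.328040 239.0082
635.866244 8.5136
643.390318 25.5803
687.735116 1.8494
690.546325 10.5859
698.358104 69.1535
716.374337 204.1107
717.393576 76.9424
719.514355 44.2115
722.332330 225.2083
758.517410 45.8232
767.388574 29.0665
771.605571 192.1814
786.370096 23.0102
793.606208 81.7689
798.378022 1130.8480
803.402117 84.9266
804.408287 38.4960
816.396068 5035.8631
817.394971 2143.7463
838.424822 119.7012
852.273497 12.9954
871.048652 34.4921
883.157059 52.4744
887.872039 192.6660
901.271340 108.0104
918.442140 69.7841
END IONS
BEGIN IONS
TITLE=sim_0002
PEPMASS=522.791536
CHARGE=2+
SEQ=IMPGAVKDIT
51.329675 21.6548
64.448432 169.4353
73.951250 221.7267
79.070126 74.5178
104.480867 68.1594
114.103085 151.0554
115.045108 89.5062
115.109160 73.5748
120.072351 440.3074
121.073091 125.5547
128.390995 2.0696
136.124614 18.8373
138.800146 141.9651
146.816865 144.3531
155.448178 450.3014
158.050273 21.6331
188.231416 164.1240
288.177914 185.1903
294.618910 21.9312
317.431100 44.3594
318.760415 16.8518
324.169570 118.2791
328.634692 25.0425
342.188833 906.1363
343.171039 401.2755
343.577841 102.1107
353.063603 6.7010
378.742033 75.9974
378.868687 138.5940
381.196878 40.9514
399.200835 247.3411
400.213491 91.5117
457.416388 73.1687
463.458961 230.1031
470.240807 452.7953
471.238449 149.0404
476.264460 1610.9148
477.260625 433.2427
480.804471 125.0290
486.589519 5.2703
496.170169 51.6867
534.726717 171.8591
556.678152 50.7579
557.318883 38.3834
569.308365 423.8345
570.312112 154.9618
574.112584 28.3659
575.332023 258.3956
576.339784 129.4123
605.690004 152.7319
638.831811 209.0386
639.072918 3.2664
667.367840 693.1356
679.404891 540.6641
697.408127 1454.0341
698.421852 428.9048
703.400160 4100.1923
704.392915 2187.5732
736.530780 107.0169
741.056432 6.6340
761.311676 53.6846
764.213740 13.4906
771.640487 4.4320
779.151275 136.3620
800.453682 1406.7886
801.455974 765.7636
810.500223 95.6713
832.888344 147.4575
840.389117 32.2746
841.814430 25.6955
843.830715 11.8796
858.520351 104.4662
889.503859 1785.1305
898.043242 63.3530
908.501932 1787.0179
913.480183 229.1936
914.470098 116.6524
920.074457 42.2883
925.533714 6535.8561
926.538606 3090.7303
931.507259 593.9142
931.970378 115.1741
932.521348 265.0290
1037.405645 73.1964
1044.041063 27.9913
END IONS
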