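wavelength_nm,HbO2,HbR,BphP1_Pfr,BphP1_Pr
600,3200,14600,254.4,226.3
605,2890.9,12157.4,373.1,471.8
610,2405.4,10316.4,533.7,937.5
615,1877.5,8903.6,744.8,1775
620,1400,7800,1014.1,3201.9
625,1017.4,6922,1347.1,5502.1
630,740.1,6207.5,1745.8,9006.2
635,554.4,5611.3,2207.5,14042.2
640,440,5100,2723.4,20854.2
645,377.4,4651.1,3278.5,29499.8
650,345.1,4255.2,3851.8,39748
655,329,3906.6,4418.1,51015.1
660,320,3600,4951.4,62372.6
665,311.7,3328.6,5429.4,72650.7
670,303.6,3079,5840.8,80630.7
675,296.2,2839,6193.8,85284.9
680,290,2600,6527.4,86002.1
685,285.7,2361.1,6922.4,82728.7
690,283.7,2139.1,7512.3,75981.6
695,284.9,1948.9,8489.1,66729.2
700,290,1800,10099.9,56175.9
705,299.6,1695.4,12627.8,45518.9
710,313.4,1625.3,16353.7,35741.2
715,330.4,1579.6,21497.3,27488.7
720,350,1550,28144.4,21044
725,371.2,1529.3,36174.4,16380.3
730,394.4,1509.3,45209.8,13259.6
735,420.4,1482,54609,11339.2
740,450,1440,63519.6,10260.9
745,483.9,1392.6,70993.2,9707.7
750,520,1410,76142,9431.6
755,555.7,1542.9,78305.6,9256.9
760,590,1670,77182.3,9072.1
765,622.4,1632.1,72891,8814.6
770,652.9,1466,65945.4,8457.2
775,681.9,1266.2,57148,7996.3
780,710,1100,47434.3,7442.8
785,737.6,995.9,37708.6,6816.7
790,765,936.4,28709.8,6141.9
795,792.3,902.5,20934.2,5443.6
800,820,880,14618.7,4745.7
805,848.1,858.7,9776.6,4069.5
810,876.2,837.7,6261.7,3432.4
815,903.8,817.8,3840.7,2847.6
820,930,800,2256.1,2323.7
825,954.4,784.9,1269.1,1865.1
830,977.2,772,683.7,1472.5
835,998.9,760.5,352.8,1143.5
840,1020,750,174.3,873.4
845,1040.9,740,82.5,656.2
850,1061.5,731.1,37.4,484.9
855,1081.3,724.2,16.2,352.5
860,1100,720,6.7,252
865,1117.2,719.1,2.7,177.2
870,1132.8,721,1,122.6
875,1147.1,724.9,0.4,83.4
880,1160,730,0.1,55.8
885,1171.7,735.6,0,36.7
890,1182.3,741.1,0,23.8
895,1191.7,746.1,0,15.1
900,1200,750,0,9.5
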