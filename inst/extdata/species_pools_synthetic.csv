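"evg","spcd","weight"
601,73,0.1538
601,113,0.141
601,116,0.1282
601,117,0.1154
601,264,0.1026
601,461,0.0897
601,531,0.0769
601,541,0.0641
601,746,0.0513
601,820,0.0385
601,832,0.0256
601,837,0.0128
602,11,0.1667
602,17,0.1515
602,20,0.1364
602,105,0.1212
602,116,0.1061
602,119,0.0909
602,263,0.0758
602,402,0.0606
602,812,0.0455
602,813,0.0303
602,832,0.0152
603,17,0.2222
603,94,0.1944
603,106,0.1667
603,316,0.1389
603,402,0.1111
603,621,0.0833
603,731,0.0556
603,922,0.0278
604,19,0.1667
604,20,0.1515
604,73,0.1364
604,103,0.1212
604,371,0.1061
604,461,0.0909
604,747,0.0758
604,813,0.0606
604,820,0.0455
604,832,0.0303
604,835,0.0152
605,20,0.1667
605,42,0.1515
605,65,0.1364
605,81,0.1212
605,93,0.1061
605,105,0.0909
605,113,0.0758
605,264,0.0606
605,402,0.0455
605,461,0.0303
605,693,0.0152
606,11,0.1333
606,64,0.1238
606,65,0.1143
606,73,0.1048
606,93,0.0952
606,264,0.0857
606,318,0.0762
606,407,0.0667
606,544,0.0571
606,746,0.0476
606,802,0.0381
606,832,0.0286
606,835,0.019
606,922,0.0095
607,15,0.1333
607,17,0.1238
607,64,0.1143
607,96,0.1048
607,113,0.0952
607,133,0.0857
607,264,0.0762
607,544,0.0667
607,611,0.0571
607,806,0.0476
607,813,0.0381
607,922,0.0286
607,970,0.019
607,972,0.0095
608,17,0.2222
608,42,0.1944
608,69,0.1667
608,103,0.1389
608,242,0.1111
608,263,0.0833
608,747,0.0556
608,901,0.0278
609,81,0.1667
609,96,0.1515
609,101,0.1364
609,103,0.1212
609,119,0.1061
609,263,0.0909
609,371,0.0758
609,544,0.0606
609,731,0.0455
609,827,0.0303
609,837,0.0152
610,17,0.1333
610,65,0.1238
610,102,0.1143
610,106,0.1048
610,202,0.0952
610,242,0.0857
610,375,0.0762
610,541,0.0667
610,611,0.0571
610,747,0.0476
610,802,0.0381
610,813,0.0286
610,832,0.019
610,837,0.0095
611,20,0.2
611,42,0.1778
611,122,0.1556
611,133,0.1333
611,242,0.1111
611,312,0.0889
611,832,0.0667
611,837,0.0444
611,972,0.0222
612,19,0.1538
612,81,0.141
612,94,0.1282
612,106,0.1154
612,242,0.1026
612,264,0.0897
612,371,0.0769
612,541,0.0641
612,806,0.0513
612,813,0.0385
612,832,0.0256
612,922,0.0128
613,11,0.2
613,69,0.1778
613,73,0.1556
613,312,0.1333
613,541,0.1111
613,621,0.0889
613,746,0.0667
613,813,0.0444
613,837,0.0222
614,11,0.2222
614,19,0.1944
614,64,0.1667
614,69,0.1389
614,101,0.1111
614,242,0.0833
614,611,0.0556
614,827,0.0278
615,15,0.1818
615,93,0.1636
615,96,0.1455
615,102,0.1273
615,119,0.1091
615,122,0.0909
615,312,0.0727
615,544,0.0545
615,746,0.0364
615,806,0.0182
616,15,0.125
616,73,0.1167
616,93,0.1083
616,101,0.1
616,105,0.0917
616,108,0.0833
616,122,0.075
616,242,0.0667
616,312,0.0583
616,318,0.05
616,531,0.0417
616,541,0.0333
616,621,0.025
616,832,0.0167
616,833,0.0083
617,20,0.1818
617,66,0.1636
617,69,0.1455
617,101,0.1273
617,116,0.1091
617,263,0.0909
617,407,0.0727
617,544,0.0545
617,812,0.0364
617,827,0.0182
618,19,0.1667
618,101,0.1515
618,105,0.1364
618,117,0.1212
618,122,0.1061
618,461,0.0909
618,621,0.0758
618,746,0.0606
618,812,0.0455
618,835,0.0303
618,922,0.0152
619,17,0.1333
619,64,0.1238
619,69,0.1143
619,81,0.1048
619,113,0.0952
619,133,0.0857
619,263,0.0762
619,264,0.0667
619,318,0.0571
619,407,0.0476
619,461,0.0381
619,544,0.0286
619,835,0.019
619,837,0.0095
620,17,0.2222
620,93,0.1944
620,103,0.1667
620,117,0.1389
620,119,0.1111
620,202,0.0833
620,375,0.0556
620,833,0.0278
621,17,0.1333
621,19,0.1238
621,94,0.1143
621,96,0.1048
621,106,0.0952
621,108,0.0857
621,133,0.0762
621,318,0.0667
621,461,0.0571
621,621,0.0476
621,731,0.0381
621,747,0.0286
621,922,0.019
621,972,0.0095
622,65,0.2222
622,96,0.1944
622,113,0.1667
622,375,0.1389
622,611,0.1111
622,820,0.0833
622,827,0.0556
622,837,0.0278
623,19,0.1538
623,93,0.141
623,117,0.1282
623,318,0.1154
623,375,0.1026
623,611,0.0897
623,731,0.0769
623,747,0.0641
623,802,0.0513
623,806,0.0385
623,813,0.0256
623,835,0.0128
624,66,0.2222
624,81,0.1944
624,103,0.1667
624,105,0.1389
624,202,0.1111
624,312,0.0833
624,611,0.0556
624,922,0.0278
625,20,0.1333
625,42,0.1238
625,66,0.1143
625,69,0.1048
625,96,0.0952
625,113,0.0857
625,117,0.0762
625,263,0.0667
625,316,0.0571
625,318,0.0476
625,461,0.0381
625,813,0.0286
625,832,0.019
625,835,0.0095
626,17,0.1667
626,19,0.1515
626,65,0.1364
626,108,0.1212
626,133,0.1061
626,202,0.0909
626,263,0.0758
626,264,0.0606
626,316,0.0455
626,318,0.0303
626,461,0.0152
627,69,0.2222
627,93,0.1944
627,113,0.1667
627,264,0.1389
627,318,0.1111
627,531,0.0833
627,813,0.0556
627,820,0.0278
628,73,0.2222
628,108,0.1944
628,122,0.1667
628,316,0.1389
628,461,0.1111
628,611,0.0833
628,693,0.0556
628,802,0.0278
629,11,0.125
629,17,0.1167
629,20,0.1083
629,42,0.1
629,65,0.0917
629,66,0.0833
629,73,0.075
629,263,0.0667
629,264,0.0583
629,371,0.05
629,461,0.0417
629,621,0.0333
629,693,0.025
629,970,0.0167
629,972,0.0083
630,19,0.1538
630,108,0.141
630,116,0.1282
630,119,0.1154
630,318,0.1026
630,375,0.0897
630,531,0.0769
630,611,0.0641
630,746,0.0513
630,802,0.0385
630,833,0.0256
630,972,0.0128
631,15,0.1667
631,17,0.1515
631,20,0.1364
631,66,0.1212
631,242,0.1061
631,375,0.0909
631,407,0.0758
631,531,0.0606
631,544,0.0455
631,827,0.0303
631,972,0.0152
632,20,0.1818
632,69,0.1636
632,96,0.1455
632,103,0.1273
632,242,0.1091
632,318,0.0909
632,375,0.0727
632,544,0.0545
632,802,0.0364
632,922,0.0182
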