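926.5768
918.2955
889.1634
869.2843
898.9305
941.2168
953.5027
995.9848
1024.2509
980.4350
963.7105
947.1566
929.1648
932.1178
927.0360
967.1199
1015.5618
1009.1623
1051.9228
1052.9971
997.5061
1000.2737
987.7393
986.0477
982.1696
973.6927
1008.3068
1011.6845
1020.9479
1040.4405
997.9162
1004.4960
1017.5464
977.0437
963.3406
963.8625
575.6550
1357.0860
983.2682
968.8455
952.8227
967.1391
945.9654
901.8549
543.7961
1285.9271
900.5879
883.5429
873.6178
860.0771
853.5723
875.6996
914.5651
914.7353
891.5801
897.6540
894.6495
877.5612
877.6937
860.6162
838.3340
851.0526
860.2532
850.5239
870.6240
912.5946
932.2304
929.3291
923.0130
915.8126
891.9673
875.8388
893.9810
908.6938
919.5399
947.9326
955.4342
970.7499
988.5651
941.9747
926.9618
923.9788
871.1439
857.2550
881.1144
896.6390
918.5870
926.4927
932.9543
956.4933
909.7199
857.2849
869.8872
880.2566
899.0650
947.0983
948.0588
938.2155
937.6892
904.4624
924.2493
971.5763
969.1480
994.3091
613.7891
1407.5755
984.0301
946.0415
564.7206
1347.5235
940.6684
933.1914
994.1888
1019.6086
957.1746
936.9061
931.8346
876.0005
864.9688
914.4057
935.4670
554.3938
1322.5659
990.3739
1001.1582
974.9884
992.4367
1014.0988
1001.8673
996.4254
964.2719
970.5503
1005.1848
987.9448
1016.6140
1036.5288
983.9277
984.1113
975.8609
945.4288
946.9382
952.4537
951.2813
934.0946
911.7428
893.5444
884.3679
914.0143
935.5889
915.5645
924.2068
906.7851
844.3935
848.5468
882.6579
881.0461
889.9763
903.2833
905.3842
937.2237
944.6584
912.4182
906.3483
906.9366
919.2589
933.7678
923.3052
931.8090
913.0027
861.7671
884.8182
924.9956
901.6721
908.7186
949.5827
942.8219
904.6949
867.5283
861.9635
885.4307
880.3112
863.9628
899.3706
941.2158
915.7864
890.5058
915.0306
545.6157
1226.2842
914.8859
967.2725
942.4818
939.5944
962.3786
953.1932
951.4445
944.1482
944.2587
963.6579
961.4988
953.7871
923.3503
897.7361
914.2144
900.0369
882.7092
903.0019
879.2237
865.9787
918.6400
922.0338
901.0313
942.0091
943.3653
930.9304
975.0064
982.4559
963.9226
976.0847
1007.5405
1038.0088
1046.5529
1049.0877
1002.7482
980.4862
1008.9516
1016.2747
1037.2117
1013.2734
980.8954
1012.2688
981.0396
938.1369
946.6613
944.7414
935.6501
935.8032
945.7813
935.1147
908.5054
936.7908
958.9964
923.3063
935.3704
973.4635
976.1928
985.3466
979.7463
961.2099
948.5541
926.6311
920.7304
926.4786
929.3314
563.0394
1315.1180
912.6812
878.0572
872.4874
864.2474
819.0543
805.1816
836.1315
836.3340
823.4449
859.6279
879.2331
855.7622
875.0153
898.0326
876.1389
863.0650
846.3111
838.6123
882.1072
921.9071
933.2592
950.4621
935.7335
953.0940
999.1377
983.0974
1005.4789
999.8308
930.6125
954.1939
964.5172
928.6031
935.1437
916.2772
897.3208
917.0063
917.0818
910.1557
913.3674
904.1209
889.5188
875.5766
867.8663
846.1028
812.9393
837.8729
918.1581
959.4144
967.7143
993.9312
983.1931
971.1324
970.8148
953.8298
939.4335
943.3890
973.3914
986.7098
993.0587
1025.9299
1025.1764
1039.3858
1042.0101
972.0005
954.6447
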