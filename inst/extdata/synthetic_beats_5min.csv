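rr,label
926.58,N
918.30,N
889.16,N
869.28,N
898.93,N
941.22,N
953.50,N
995.98,N
1024.25,N
980.44,N
963.71,N
947.16,N
929.16,N
932.12,N
927.04,N
967.12,N
1015.56,N
1009.16,N
1051.92,N
1053.00,N
997.51,N
1000.27,N
987.74,N
986.05,N
982.17,N
973.69,N
1008.31,N
1011.68,N
1020.95,N
1040.44,N
997.92,N
1004.50,N
1017.55,N
977.04,N
963.34,N
963.86,N
575.65,V
1357.09,V
983.27,N
968.85,N
952.82,N
967.14,N
945.97,N
901.85,N
543.80,V
1285.93,V
900.59,N
883.54,N
873.62,N
860.08,N
853.57,N
875.70,N
914.57,N
914.74,N
891.58,N
897.65,N
894.65,N
877.56,N
877.69,N
860.62,N
838.33,N
851.05,N
860.25,N
850.52,N
870.62,N
912.59,N
932.23,N
929.33,N
923.01,N
915.81,N
891.97,N
875.84,N
893.98,N
908.69,N
919.54,N
947.93,N
955.43,N
970.75,N
988.57,N
941.97,N
926.96,N
923.98,N
871.14,N
857.26,N
881.11,N
896.64,N
918.59,N
926.49,N
932.95,N
956.49,N
909.72,N
857.28,N
869.89,N
880.26,N
899.07,N
947.10,N
948.06,N
938.22,N
937.69,N
904.46,N
924.25,N
971.58,N
969.15,N
994.31,N
613.79,V
1407.58,V
984.03,N
946.04,N
564.72,V
1347.52,V
940.67,N
933.19,N
994.19,N
1019.61,N
957.17,N
936.91,N
931.83,N
876.00,N
864.97,N
914.41,N
935.47,N
554.39,V
1322.57,V
990.37,N
1001.16,N
974.99,N
992.44,N
1014.10,N
1001.87,N
996.43,N
964.27,N
970.55,N
1005.18,N
987.94,N
1016.61,N
1036.53,N
983.93,N
984.11,N
975.86,N
945.43,N
946.94,N
952.45,N
951.28,N
934.09,N
911.74,N
893.54,N
884.37,N
914.01,N
935.59,N
915.56,N
924.21,N
906.79,N
844.39,N
848.55,N
882.66,N
881.05,N
889.98,N
903.28,N
905.38,N
937.22,N
944.66,N
912.42,N
906.35,N
906.94,N
919.26,N
933.77,N
923.31,N
931.81,N
913.00,N
861.77,N
884.82,N
925.00,N
901.67,N
908.72,N
949.58,N
942.82,N
904.69,N
867.53,N
861.96,N
885.43,N
880.31,N
863.96,N
899.37,N
941.22,N
915.79,N
890.51,N
915.03,N
545.62,V
1226.28,V
914.89,N
967.27,N
942.48,N
939.59,N
962.38,N
953.19,N
951.44,N
944.15,N
944.26,N
963.66,N
961.50,N
953.79,N
923.35,N
897.74,N
914.21,N
900.04,N
882.71,N
903.00,N
879.22,N
865.98,N
918.64,N
922.03,N
901.03,N
942.01,N
943.37,N
930.93,N
975.01,N
982.46,N
963.92,N
976.08,N
1007.54,N
1038.01,N
1046.55,N
1049.09,N
1002.75,N
980.49,N
1008.95,N
1016.27,N
1037.21,N
1013.27,N
980.90,N
1012.27,N
981.04,N
938.14,N
946.66,N
944.74,N
935.65,N
935.80,N
945.78,N
935.11,N
908.51,N
936.79,N
959.00,N
923.31,N
935.37,N
973.46,N
976.19,N
985.35,N
979.75,N
961.21,N
948.55,N
926.63,N
920.73,N
926.48,N
929.33,N
563.04,V
1315.12,V
912.68,N
878.06,N
872.49,N
864.25,N
819.05,N
805.18,N
836.13,N
836.33,N
823.44,N
859.63,N
879.23,N
855.76,N
875.02,N
898.03,N
876.14,N
863.06,N
846.31,N
838.61,N
882.11,N
921.91,N
933.26,N
950.46,N
935.73,N
953.09,N
999.14,N
983.10,N
1005.48,N
999.83,N
930.61,N
954.19,N
964.52,N
928.60,N
935.14,N
916.28,N
897.32,N
917.01,N
917.08,N
910.16,N
913.37,N
904.12,N
889.52,N
875.58,N
867.87,N
846.10,N
812.94,N
837.87,N
918.16,N
959.41,N
967.71,N
993.93,N
983.19,N
971.13,N
970.81,N
953.83,N
939.43,N
943.39,N
973.39,N
986.71,N
993.06,N
1025.93,N
1025.18,N
1039.39,N
1042.01,N
972.00,N
954.64,N
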