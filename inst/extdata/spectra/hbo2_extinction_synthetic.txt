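# chromophore: HbO2
# source: synthetic reconstruction: molar extinction (cm^-1 M^-1); anchors transcribed from the standard compiled oxyhemoglobin tabulation, natural-spline interpolated to a 2 nm grid
# columns: wavelength_nm, value
640, 442
642, 426.139
644, 410.543
646, 395.478
648, 381.208
650, 368
652, 356.061
654, 345.37
656, 335.848
658, 327.418
660, 320
662, 313.506
664, 307.803
666, 302.747
668, 298.193
670, 294
672, 290.059
674, 286.411
676, 283.134
678, 280.304
680, 278
682, 276.289
684, 275.208
686, 274.781
688, 275.037
690, 276
692, 277.679
694, 280.006
696, 282.893
698, 286.253
700, 290
702, 294.066
704, 298.465
706, 303.231
708, 308.398
710, 314
712, 320.057
714, 326.535
716, 333.383
718, 340.555
720, 348
722, 355.689
724, 363.668
726, 372.003
728, 380.759
730, 390
732, 399.794
734, 410.216
736, 421.34
738, 433.243
740, 446
742, 459.63
744, 473.917
746, 488.59
748, 503.375
750, 518
752, 532.246
754, 546.115
756, 559.66
758, 572.936
760, 586
762, 598.905
764, 611.704
766, 624.451
768, 637.199
770, 650
772, 662.854
774, 675.548
776, 687.815
778, 699.388
780, 710
782, 719.518
784, 728.342
786, 737.008
788, 746.049
790, 756
792, 767.219
794, 779.355
796, 791.883
798, 804.273
800, 816
802, 826.678
804, 836.492
806, 845.766
808, 854.827
810, 864
812, 873.555
814, 883.54
816, 893.948
818, 904.77
820, 916
822, 927.597
824, 939.395
826, 951.194
828, 962.795
830, 974
832, 984.649
834, 994.737
836, 1004.3
838, 1013.38
840, 1022
842, 1030.19
844, 1037.93
846, 1045.17
848, 1051.87
850, 1058
852, 1063.58
854, 1068.91
856, 1074.35
858, 1080.26
860, 1087
862, 1094.79
864, 1103.28
866, 1111.97
868, 1120.38
870, 1128
872, 1134.48
874, 1140
876, 1144.88
878, 1149.44
880, 1154
882, 1158.8
884, 1163.76
886, 1168.72
888, 1173.52
890, 1178
892, 1182.06
894, 1185.87
896, 1189.65
898, 1193.62
900, 1198
902, 1202.93
904, 1208.14
906, 1213.3
908, 1218.03
910, 1222
912, 1224.98
914, 1227.25
916, 1229.24
918, 1231.35
920, 1234
922, 1237.4
924, 1240.93
926, 1243.76
928, 1245.06
930, 1244
932, 1240.07
934, 1234.02
936, 1226.95
938, 1219.91
940, 1214
942, 1210.01
944, 1207.61
946, 1206.21
948, 1205.21
950, 1204
952, 1202.11
954, 1199.6
956, 1196.62
958, 1193.36
960, 1190
962, 1186.64
964, 1183.16
966, 1179.35
968, 1175.03
970, 1170
972, 1164.16
974, 1157.77
976, 1151.21
978, 1144.83
980, 1139
982, 1134.06
984, 1130.26
986, 1127.83
988, 1127
990, 1128
992, 1130.91
994, 1135.23
996, 1140.29
998, 1145.43
1000, 1150
1002, 1153.48
1004, 1155.98
1006, 1157.73
1008, 1158.99
1010, 1160
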