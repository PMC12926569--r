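# chromophore: Hb
# source: synthetic reconstruction: molar extinction (cm^-1 M^-1); anchors transcribed from the standard compiled deoxyhemoglobin tabulation, natural-spline interpolated to a 2 nm grid
# columns: wavelength_nm, value
640, 4329
642, 4211.43
644, 4094.29
646, 3978.05
648, 3863.14
650, 3750
652, 3639.08
654, 3530.86
656, 3425.79
658, 3324.34
660, 3227
662, 3134.04
664, 3045
666, 2959.24
668, 2876.12
670, 2795
672, 2715.31
674, 2636.82
676, 2559.37
678, 2482.82
680, 2407
682, 2331.9
684, 2258.07
686, 2186.19
688, 2116.94
690, 2051
692, 1989.05
694, 1931.74
696, 1879.71
698, 1833.58
700, 1794
702, 1761.35
704, 1735.01
706, 1714.09
708, 1697.71
710, 1685
712, 1675.09
714, 1667.2
716, 1660.57
718, 1654.42
720, 1648
722, 1640.53
724, 1631.21
726, 1619.22
728, 1603.76
730, 1584
732, 1559.57
734, 1531.8
736, 1502.44
738, 1473.25
740, 1446
742, 1422.48
744, 1404.63
746, 1394.44
748, 1393.9
750, 1405
752, 1428.72
754, 1462.05
756, 1501
758, 1539.22
760, 1561
762, 1552.3
764, 1515.25
766, 1456.1
768, 1384.21
770, 1312
772, 1249.53
774, 1196.99
776, 1152.08
778, 1112.51
780, 1076
782, 1040.61
784, 1005.84
786, 971.571
788, 937.668
790, 904
792, 870.654
794, 838.597
796, 809.012
798, 783.085
800, 762
802, 746.52
804, 735.724
806, 728.268
808, 722.807
810, 718
812, 712.792
814, 707.29
816, 701.893
818, 696.997
820, 693
822, 690.203
824, 688.518
826, 687.761
828, 687.748
830, 688.296
832, 689.221
834, 690.337
836, 691.462
838, 692.411
840, 693
842, 693.1
844, 692.804
846, 692.257
848, 691.607
850, 691
852, 690.561
854, 690.328
856, 690.313
858, 690.532
860, 691
862, 691.726
864, 692.702
866, 693.915
868, 695.354
870, 697.004
872, 698.855
874, 700.892
876, 703.104
878, 705.477
880, 708
882, 710.652
884, 713.381
886, 716.13
888, 718.84
890, 721.453
892, 723.909
894, 726.15
896, 728.118
898, 729.754
900, 731
902, 731.812
904, 732.205
906, 732.211
908, 731.861
910, 731.185
912, 730.214
914, 728.979
916, 727.512
918, 725.842
920, 724
922, 722.008
924, 719.846
926, 717.487
928, 714.9
930, 712.058
932, 708.93
934, 705.49
936, 701.707
938, 697.553
940, 693
942, 688.036
944, 682.721
946, 677.135
948, 671.355
950, 665.46
952, 659.528
954, 653.638
956, 647.868
958, 642.295
960, 637
962, 632.028
964, 627.3
966, 622.707
968, 618.136
970, 613.477
972, 608.621
974, 603.455
976, 597.871
978, 591.756
980, 585
982, 577.539
984, 569.493
986, 561.028
988, 552.31
990, 543.506
992, 534.781
994, 526.301
996, 518.234
998, 510.745
1000, 504
1002, 498.107
1004, 492.943
1006, 488.325
1008, 484.072
1010, 480
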