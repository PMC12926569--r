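# chromophore: collagen
# source: synthetic reconstruction: mass-basis absorption coefficient (cm^-1); anchor points shaped to the published NIR-I collagen feature set (max 690 nm, local min ~850 nm, local max ~910 nm, local min ~940 nm), natural-spline interpolated to a 2 nm grid
# columns: wavelength_nm, value
640, 0.435
642, 0.440254
644, 0.445445
646, 0.450509
648, 0.455382
650, 0.46
652, 0.464324
654, 0.468408
656, 0.47233
658, 0.476168
660, 0.48
662, 0.48389
664, 0.487843
666, 0.491852
668, 0.495907
670, 0.5
672, 0.504133
674, 0.508347
676, 0.512694
678, 0.517228
680, 0.522
682, 0.526978
684, 0.531795
686, 0.536
688, 0.539045
690, 0.54
692, 0.538271
694, 0.535
696, 0.531476
698, 0.527852
700, 0.524
702, 0.519815
704, 0.515297
706, 0.510471
708, 0.505364
710, 0.5
712, 0.494408
714, 0.488623
716, 0.482684
718, 0.476628
720, 0.470495
722, 0.464323
724, 0.458149
726, 0.452011
728, 0.445949
730, 0.44
732, 0.434192
734, 0.428513
736, 0.42294
738, 0.417451
740, 0.412022
742, 0.406632
744, 0.401257
746, 0.395875
748, 0.390464
750, 0.385
752, 0.379469
754, 0.373885
756, 0.368271
758, 0.362649
760, 0.357041
762, 0.35147
764, 0.345958
766, 0.340527
768, 0.335201
770, 0.33
772, 0.324943
774, 0.320028
776, 0.315247
778, 0.310595
780, 0.306065
782, 0.301649
784, 0.297341
786, 0.293135
788, 0.289024
790, 0.285
792, 0.28106
794, 0.277205
796, 0.27344
798, 0.269771
800, 0.266201
802, 0.262735
804, 0.259377
806, 0.256132
808, 0.253005
810, 0.25
812, 0.247119
814, 0.244353
816, 0.241691
818, 0.239121
820, 0.236632
822, 0.234213
824, 0.231851
826, 0.229536
828, 0.227256
830, 0.225
832, 0.222765
834, 0.220583
836, 0.218496
838, 0.216545
840, 0.214771
842, 0.213215
844, 0.211919
846, 0.210923
848, 0.21027
850, 0.21
852, 0.210142
854, 0.210675
856, 0.211565
858, 0.21278
860, 0.214285
862, 0.216048
864, 0.218034
866, 0.22021
868, 0.222543
870, 0.225
872, 0.227557
874, 0.230237
876, 0.233073
878, 0.236095
880, 0.239338
882, 0.242834
884, 0.246616
886, 0.250716
888, 0.255166
890, 0.26
892, 0.265213
894, 0.270655
896, 0.27614
898, 0.281479
900, 0.286486
902, 0.290975
904, 0.294757
906, 0.297647
908, 0.299457
910, 0.3
912, 0.299149
914, 0.297016
916, 0.293771
918, 0.289585
920, 0.28463
922, 0.279077
924, 0.273097
926, 0.266862
928, 0.260576
930, 0.254474
932, 0.248793
934, 0.243768
936, 0.239637
938, 0.236635
940, 0.235
942, 0.234896
944, 0.236202
946, 0.238726
948, 0.242275
950, 0.246658
952, 0.251682
954, 0.257155
956, 0.262889
958, 0.268806
960, 0.274936
962, 0.281313
964, 0.287973
966, 0.294951
968, 0.302282
970, 0.31
972, 0.318132
974, 0.326668
976, 0.335589
978, 0.344877
980, 0.354513
982, 0.364477
984, 0.374752
986, 0.385317
988, 0.396111
990, 0.407033
992, 0.417982
994, 0.428856
996, 0.439552
998, 0.449967
1000, 0.46
1002, 0.469582
1004, 0.478775
1006, 0.487679
1008, 0.496388
1010, 0.505
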