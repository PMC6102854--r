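feature_id	well_type	cell_line	replicate	plate	readout
siRNA_01	lib	HAP1	HAP1_r1	P1	0.8589
siRNA_02	lib	HAP1	HAP1_r1	P1	0.7452
siRNA_03	lib	HAP1	HAP1_r1	P1	0.4121
siRNA_04	lib	HAP1	HAP1_r1	P1	0.5286
siRNA_05	lib	HAP1	HAP1_r1	P1	0.7443
siRNA_06	lib	HAP1	HAP1_r1	P1	0.3201
siRNA_07	lib	HAP1	HAP1_r1	P1	0.673
siRNA_08	lib	HAP1	HAP1_r1	P1	0.9888
scr_1_1	neg	HAP1	HAP1_r1	P1	0.9667
scr_1_2	neg	HAP1	HAP1_r1	P1	0.8742
scr_1_3	neg	HAP1	HAP1_r1	P1	0.9632
scr_1_4	neg	HAP1	HAP1_r1	P1	0.949
plk1_1_1	pos	HAP1	HAP1_r1	P1	0.1557
plk1_1_2	pos	HAP1	HAP1_r1	P1	0.1263
plk1_1_3	pos	HAP1	HAP1_r1	P1	0.1296
plk1_1_4	pos	HAP1	HAP1_r1	P1	0.1135
siRNA_09	lib	HAP1	HAP1_r1	P2	1.4299
siRNA_10	lib	HAP1	HAP1_r1	P2	1.2484
siRNA_11	lib	HAP1	HAP1_r1	P2	1.4285
siRNA_12	lib	HAP1	HAP1_r1	P2	1.2121
siRNA_13	lib	HAP1	HAP1_r1	P2	1.1043
siRNA_14	lib	HAP1	HAP1_r1	P2	1.5814
siRNA_15	lib	HAP1	HAP1_r1	P2	1.8288
siRNA_16	lib	HAP1	HAP1_r1	P2	1.2403
scr_2_1	neg	HAP1	HAP1_r1	P2	1.8308
scr_2_2	neg	HAP1	HAP1_r1	P2	1.8109
scr_2_3	neg	HAP1	HAP1_r1	P2	1.7598
scr_2_4	neg	HAP1	HAP1_r1	P2	1.8345
plk1_2_1	pos	HAP1	HAP1_r1	P2	0.9336
plk1_2_2	pos	HAP1	HAP1_r1	P2	0.9418
plk1_2_3	pos	HAP1	HAP1_r1	P2	0.8804
plk1_2_4	pos	HAP1	HAP1_r1	P2	1.0233
siRNA_01	lib	HAP1	HAP1_r2	P1	0.7154
siRNA_02	lib	HAP1	HAP1_r2	P1	0.4891
siRNA_03	lib	HAP1	HAP1_r2	P1	1.0774
siRNA_04	lib	HAP1	HAP1_r2	P1	0.806
siRNA_05	lib	HAP1	HAP1_r2	P1	1.0666
siRNA_06	lib	HAP1	HAP1_r2	P1	1.0091
siRNA_07	lib	HAP1	HAP1_r2	P1	0.7185
siRNA_08	lib	HAP1	HAP1_r2	P1	0.8727
scr_1_1	neg	HAP1	HAP1_r2	P1	1.0323
scr_1_2	neg	HAP1	HAP1_r2	P1	1.0863
scr_1_3	neg	HAP1	HAP1_r2	P1	0.9736
scr_1_4	neg	HAP1	HAP1_r2	P1	1.0083
plk1_1_1	pos	HAP1	HAP1_r2	P1	0.1373
plk1_1_2	pos	HAP1	HAP1_r2	P1	0.1666
plk1_1_3	pos	HAP1	HAP1_r2	P1	0.1591
plk1_1_4	pos	HAP1	HAP1_r2	P1	0.2082
siRNA_09	lib	HAP1	HAP1_r2	P2	1.6789
siRNA_10	lib	HAP1	HAP1_r2	P2	1.7863
siRNA_11	lib	HAP1	HAP1_r2	P2	1.249
siRNA_12	lib	HAP1	HAP1_r2	P2	1.6062
siRNA_13	lib	HAP1	HAP1_r2	P2	1.6745
siRNA_14	lib	HAP1	HAP1_r2	P2	1.5334
siRNA_15	lib	HAP1	HAP1_r2	P2	1.2638
siRNA_16	lib	HAP1	HAP1_r2	P2	1.82
scr_2_1	neg	HAP1	HAP1_r2	P2	1.7421
scr_2_2	neg	HAP1	HAP1_r2	P2	1.8389
scr_2_3	neg	HAP1	HAP1_r2	P2	1.7398
scr_2_4	neg	HAP1	HAP1_r2	P2	1.8153
plk1_2_1	pos	HAP1	HAP1_r2	P2	0.9083
plk1_2_2	pos	HAP1	HAP1_r2	P2	1.0209
plk1_2_3	pos	HAP1	HAP1_r2	P2	0.9856
plk1_2_4	pos	HAP1	HAP1_r2	P2	0.9299
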