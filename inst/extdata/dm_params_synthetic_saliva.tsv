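# theta 0.008
taxon	pi
t1	0.274236
t2	0.108721
t3	0.098414
t4	0.060533
t5	0.156507
t6	0.062408
t7	0.049645
t8	0.027275
t9	0.020631
t10	0.03344
t11	0.014858
t12	0.012281
t13	0.015605
t14	0.010394
t15	0.020924
t16	0.005832
t17	0.008483
t18	0.00744
t19	0.006595
t20	0.004958
t21	0.00082
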