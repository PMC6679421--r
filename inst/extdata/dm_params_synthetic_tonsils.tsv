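# theta 0.011
taxon	pi
t1	0.083544
t2	0.238259
t3	0.076955
t4	0.042903
t5	0.088511
t6	0.079889
t7	0.063535
t8	0.040361
t9	0.031591
t10	0.052032
t11	0.034837
t12	0.048212
t13	0.015663
t14	0.031817
t15	0.025604
t16	0.012838
t17	0.007043
t18	0.00569
t19	0.010639
t20	0.007792
t21	0.002285
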