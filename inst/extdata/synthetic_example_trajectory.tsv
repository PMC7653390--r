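timeStep	pedestrianId	x	y
1	1	1.7	0.5
1	2	1.3	2.6000000000000001
2	1	1.7	0.55359999999999998
2	2	1.3	2.6240000000000001
3	1	1.7	0.60719999999999996
3	2	1.3	2.6480000000000001
4	1	1.7	0.66080000000000005
4	2	1.3	2.6720000000000002
5	1	1.7	0.71440000000000003
5	2	1.3	2.6960000000000002
6	1	1.7	0.76800000000000002
6	2	1.3	2.7200000000000002
7	1	1.7	0.8216
7	2	1.3	2.7440000000000002
8	1	1.7	0.87519999999999998
8	2	1.3	2.7680000000000002
9	1	1.7	0.92880000000000007
9	2	1.3	2.7920000000000003
10	1	1.7	0.98239999999999994
10	2	1.3	2.8000000000000003
11	1	1.7	1.036
11	2	1.3	2.7760000000000002
12	1	1.7	1.0895999999999999
12	2	1.3	2.7520000000000002
13	1	1.7	1.1432
13	2	1.3	2.7280000000000002
14	1	1.7	1.1968000000000001
14	2	1.3	2.7040000000000002
15	1	1.7	1.2504
15	2	1.3	2.6800000000000002
16	1	1.7	1.304
16	2	1.3	2.6560000000000001
17	1	1.7	1.3576000000000001
17	2	1.3	2.6320000000000001
18	1	1.7	1.4112
18	2	1.3	2.6080000000000001
19	1	1.7	1.4647999999999999
19	2	1.3	2.6000000000000001
20	1	1.7	1.5184
20	2	1.3	2.6000000000000001
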