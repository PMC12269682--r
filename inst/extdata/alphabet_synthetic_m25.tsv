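state_label	point_index	x	y	z
1	1	0	0	0
1	2	1.32819	3.41124	-1.01947
1	3	-1.64356	3.40415	-3.38773
1	4	-0.138742	5.43771	-6.22325
2	1	0	0	0
2	2	3.03817	-1.51214	-1.70967
2	3	4.66069	1.19681	-3.82367
2	4	7.18856	3.8165	-4.91322
3	1	0	0	0
3	2	3.34592	1.59293	0.841063
3	3	6.82343	2.48056	-0.407549
3	4	8.10055	1.80861	-3.92286
4	1	0	0	0
4	2	3.01421	2.13275	0.897733
4	3	6.13898	3.13685	2.81283
4	4	9.27672	5.26726	3.04926
5	1	0	0	0
5	2	3.09547	1.42577	1.68084
5	3	5.45004	4.21644	2.73355
5	4	6.11418	5.4937	6.2503
6	1	0	0	0
6	2	2.44502	1.63005	-2.40931
6	3	5.29199	3.96544	-3.34778
6	4	8.87972	5.20751	-3.50744
7	1	0	0	0
7	2	-0.209114	-1.41356	-3.5211
7	3	-0.323357	-3.74727	-6.51788
7	4	-1.06195	-5.96385	-9.51476
8	1	0	0	0
8	2	3.57423	1.10225	0.670782
8	3	6.33768	-0.431742	2.78033
8	4	8.30511	0.136456	5.98133
9	1	0	0	0
9	2	2.8612	-2.33296	0.900457
9	3	3.21034	-6.06704	1.51259
9	4	6.20623	-8.26191	2.31711
10	1	0	0	0
10	2	3.19048	-1.04848	1.77808
10	3	3.50627	2.08912	3.89841
10	4	6.14466	4.03246	5.82255
11	1	0	0	0
11	2	3.36589	-0.44808	-1.70587
11	3	7.09015	-1.09935	-1.32413
11	4	8.05388	-3.51777	-4.09225
12	1	0	0	0
12	2	2.7673	2.59792	0.18132
12	3	6.38757	2.90234	1.29529
12	4	10.1204	2.4839	0.720074
13	1	0	0	0
13	2	3.41731	-0.553466	1.56706
13	3	6.44898	1.73621	1.64687
13	4	7.85252	1.26406	5.14647
14	1	0	0	0
14	2	2.96184	-2.38055	0.0228616
14	3	2.85167	1.40222	-0.321439
14	4	5.12649	2.93288	-2.95246
15	1	0	0	0
15	2	1.79403	-3.23035	-0.886716
15	3	2.42674	-4.48909	-4.41592
15	4	0.345709	-3.54778	-7.45289
16	1	0	0	0
16	2	1.84163	-3.25452	-0.675636
16	3	4.43453	-3.76621	2.05476
16	4	6.07483	-2.68875	5.30875
17	1	0	0	0
17	2	3.47303	-1.53015	-0.191654
17	3	6.77732	-2.45235	-1.82602
17	4	9.63486	-1.89868	-4.26896
18	1	0	0	0
18	2	3.77285	0.444936	0.0874629
18	3	7.37526	1.57236	0.52509
18	4	9.87604	4.32733	1.29726
19	1	0	0	0
19	2	3.10679	-1.04465	1.92265
19	3	6.39763	-2.9443	1.96393
19	4	9.23201	-3.43756	-0.518609
20	1	0	0	0
20	2	3.00285	1.37412	-1.88007
20	3	3.50388	-0.729009	-5.0051
20	4	4.52195	-1.68771	-8.53843
21	1	0	0	0
21	2	1.20424	-2.50845	-2.58795
21	3	2.09013	-6.14377	-3.25105
21	4	1.83683	-8.66455	-6.08326
22	1	0	0	0
22	2	3.65795	-0.148201	-1.01854
22	3	6.15572	0.23225	1.81985
22	4	5.43992	0.132475	5.55049
23	1	0	0	0
23	2	2.63097	1.02798	-2.5419
23	3	3.50156	1.83173	-6.15244
23	4	6.21485	3.06496	-8.50983
24	1	0	0	0
24	2	-2.55477	-1.99326	1.98496
24	3	-6.34634	-2.23322	2.06518
24	4	-8.47571	-0.305769	4.5533
25	1	0	0	0
25	2	3.19741	-0.558752	-1.97594
25	3	6.07058	-2.78112	-3.09218
25	4	9.1349	-5.01784	-2.87528
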