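"age","qx"
12,0.000102
13,0.000104435633427826
14,0.000107140917319048
15,0.000110145704841054
16,0.00011348315422361
17,0.00011719009466434
18,0.000121307432743816
19,0.000125880603835111
20,0.000130960073489184
21,0.000136601894328943
22,0.00014286832459739
23,0.000149828515185607
24,0.000157559272722038
25,0.00016614590714384
26,0.00017568317310338
27,0.000186276315598426
28,0.000198042231364683
29,0.000211110758846817
30,0.000225626110982948
31,0.000241748466613597
32,0.000259655738076488
33,0.000279545534492841
34,0.000301637342410299
35,0.00032617494786616
36,0.000353429126598706
37,0.000383700632093476
38,0.000417323514437958
39,0.000454668806608716
40,0.000496148618869611
41,0.000542220686463349
42,0.00059339342078074
43,0.000650231519747979
44,0.000713362199343339
45,0.000783482115008872
46,0.000861365049335826
47,0.000947870450858411
48,0.00104395291818263
49,0.00115067273410879
50,0.00126920756599318
51,0.00140086546146391
52,0.00154709928290035
53,0.00170952273996267
54,0.00188992819709244
55,0.00209030645249254
56,0.00231286870685
57,0.00256007096422952
58,0.00283464113440484
59,0.00313960913570573
60,0.0034783403305696
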