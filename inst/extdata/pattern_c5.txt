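time_s
0.128131
0.139721
0.153189
0.254656
0.266403
0.429291
0.507098
0.516871
0.533688
0.549446
0.890178
0.900213
1.003757
1.133051
1.136113
1.140580
1.146845
1.269331
1.274174
1.278862
1.282953
1.286118
1.388001
1.402930
1.415358
1.534434
1.547097
1.628762
1.645668
1.755348
2.015535
2.032177
2.520874
2.532104
2.631331
2.648538
2.759859
2.775235
2.887517
3.018188
3.254423
3.532473
3.635397
3.691556
3.752474
3.884105
4.007841
4.145750
4.258627
4.271347
4.281051
4.393607
4.501435
4.517439
4.636218
4.815842
4.875245
4.880866
4.888291
5.129952
5.146564
5.162790
5.380233
5.397987
5.554043
5.647617
5.650659
5.654618
5.880046
5.892891
5.908966
6.001421
6.014492
6.023539
6.026258
6.033307
6.049025
6.131069
6.145564
6.162434
6.633411
6.646788
6.769085
6.903406
6.918173
7.000805
7.045936
7.141862
7.271948
7.401112
8.084857
8.129759
8.142073
8.154981
8.751063
8.943053
9.006109
9.019842
9.262556
9.277873
9.509487
9.527218
9.631646
9.643631
9.651657
9.665831
10.013015
10.129352
10.143953
10.258562
10.380380
10.383241
10.393926
10.403471
10.412209
10.528937
10.762180
10.888545
10.902275
10.917194
11.130421
11.141348
11.155470
11.260086
11.271789
11.280488
11.392899
11.407213
11.420971
11.500751
11.509538
11.516559
11.763987
11.776945
11.788533
11.800979
11.890356
12.003020
12.015954
12.131335
12.525439
12.540173
12.552467
12.878890
12.895618
12.906509
12.920014
13.012167
13.021744
13.024389
13.134311
13.258672
13.263411
13.266447
13.270866
13.389434
13.402988
13.500165
13.631167
13.640313
13.645319
13.887758
13.901203
14.016612
14.031080
14.048758
14.140567
14.144166
14.157583
14.262024
14.276982
14.387432
14.402869
14.502751
14.515171
14.629484
14.755025
14.770052
14.778377
15.255986
15.268354
15.281684
15.293895
15.394032
15.411406
15.415138
15.463513
15.467260
15.470192
15.473064
15.475569
15.478602
15.683788
15.770690
15.890910
15.904869
16.010329
16.013461
16.017308
16.021274
16.140390
16.254559
16.272443
16.282018
16.507332
16.625363
16.637168
16.754951
16.766906
16.886005
16.900539
16.913149
16.928198
17.005038
17.018859
17.129241
17.140272
17.155951
17.250947
17.254479
17.379385
17.510718
17.522848
17.538798
17.753038
17.769125
17.783482
18.008276
18.142969
18.160162
18.174662
18.262029
18.270210
18.325381
18.502907
18.515413
18.523881
18.534862
18.537509
18.541201
18.632536
18.647623
18.660522
18.684136
18.889576
19.002801
19.194062
19.251194
19.276324
19.394817
19.411109
19.421841
19.499351
19.502510
19.517605
19.632646
19.887818
19.900365
19.911814
20.003284
20.015152
20.033061
20.400584
20.418093
20.428795
20.526571
20.542565
20.557699
20.627658
21.011205
21.375662
21.384767
21.394765
21.409902
21.533509
21.543710
21.662562
21.768151
22.003554
22.139951
22.156171
22.504267
22.519039
22.656093
22.742646
22.880534
22.890876
23.127170
23.140099
23.375493
23.388984
23.398955
23.519902
23.535429
23.764363
23.926965
23.931311
23.935520
23.939542
23.942578
24.010764
24.026185
24.137385
24.149770
24.254077
24.263886
24.380341
24.384720
24.413081
24.507240
24.520999
24.654778
24.664356
24.674931
24.690240
24.760642
24.883464
24.898744
25.384093
25.506076
25.515745
25.525021
25.629510
25.633991
25.646122
25.660089
25.754168
25.886249
25.895186
26.264627
26.382367
26.385933
26.506790
26.644653
26.654850
26.719031
26.721735
26.724819
26.729577
26.732325
26.735216
26.740165
26.743804
26.747204
26.750050
26.753387
26.764868
26.773207
26.875486
26.887381
27.139296
27.149902
27.263549
27.272771
27.394854
27.408874
27.419909
27.430964
27.439212
27.626671
28.007365
28.256815
28.272448
28.277226
28.280731
28.283726
28.385923
28.398432
28.639375
28.653207
28.663791
28.761848
28.773377
28.778622
28.786303
28.796595
29.132073
29.257904
29.273377
29.378797
29.500302
29.508998
29.513483
29.879980
29.889450
29.893512
30.049001
30.052090
30.259175
30.268874
30.396569
30.512274
30.528503
30.540510
30.641816
30.659349
30.877851
31.004766
31.017712
31.035401
31.046806
31.131365
31.134996
31.260251
31.392270
31.401403
31.414615
31.418878
31.425039
31.625580
31.636956
31.646375
31.753755
31.764148
31.966388
32.007101
32.023706
32.126061
32.143498
32.246560
32.383329
32.400300
32.511215
32.528743
32.538604
32.555200
32.632556
32.644690
32.691418
32.703781
32.759587
32.877493
32.894309
32.898989
32.901667
32.905556
32.910496
33.000391
33.010951
33.016002
33.020916
33.023532
33.129770
33.142441
33.158903
33.389297
33.404516
33.419136
33.422523
33.631969
33.646876
33.764799
33.875644
33.884505
34.008787
34.025462
34.037272
34.129308
34.379821
34.389314
34.525577
34.536271
34.752609
34.770493
34.787435
34.795622
34.810525
34.906847
34.917761
35.009474
35.026081
35.039837
35.135094
35.394680
35.406039
35.755629
35.769861
35.783529
35.799865
36.003745
36.016722
36.030608
36.046905
36.130796
36.135717
36.141806
36.152362
36.254167
36.271727
36.286688
36.386769
36.391728
36.402333
36.505653
36.632860
36.647144
36.663988
36.678694
36.776136
36.883651
36.895816
36.994060
37.001241
37.015099
37.400452
37.541392
37.636565
37.649153
37.758281
38.144397
38.155230
38.172498
38.196201
38.260522
38.272333
38.635961
38.751654
38.884625
38.899941
39.009315
39.013147
39.016717
39.131530
39.255548
39.386934
39.402587
39.505240
39.632393
39.649592
39.769453
40.131359
40.257664
40.392294
40.394923
40.408971
40.413850
40.648080
40.660059
40.676023
40.753643
40.757698
40.766231
40.891056
41.007267
41.138650
41.254045
41.504285
41.512746
41.528260
41.538504
41.648777
41.715891
41.773174
41.877293
41.892984
41.910684
42.009999
42.044656
42.135427
42.150029
42.167906
42.177107
42.266015
42.275694
42.290299
42.293116
42.296219
42.381050
42.394236
42.512360
42.635912
42.764390
42.885293
42.900357
42.911613
42.949263
43.003653
43.019465
43.032867
43.130785
43.142300
43.273365
43.283163
43.500229
43.514527
43.525449
43.542814
43.553042
43.633750
43.645571
43.648322
43.651248
43.654272
43.880686
44.002758
44.008278
44.018478
44.142738
44.159376
44.206054
44.392895
44.401625
44.502033
44.632717
44.644280
45.007357
45.023490
45.038980
45.055334
45.131726
45.275805
45.515659
45.519071
45.771746
45.779859
45.784201
45.876549
45.890359
45.906286
45.922425
46.003910
46.012077
46.126495
46.139031
46.151226
46.256531
46.270287
46.283119
46.504690
46.638283
46.647601
46.836054
46.878747
46.906061
47.010994
47.028665
47.045776
47.399353
47.417069
47.518187
47.568076
47.572493
47.575814
47.578622
47.583465
47.587439
47.592374
47.596657
47.601656
47.604739
47.609350
47.612275
47.628922
47.637650
47.755244
47.766573
47.769657
47.822035
47.886023
48.001495
48.009753
48.256761
48.269527
48.279109
48.292568
49.006112
49.012260
49.016838
49.030618
49.043898
49.262289
49.274033
49.288839
49.627622
49.636913
49.753102
49.875399
49.884090
50.000859
50.137370
50.151581
50.382919
50.391858
50.524454
50.535373
50.553146
50.556493
50.559012
50.563483
50.567566
50.571031
50.575805
50.634434
50.751563
50.766311
50.781506
50.810555
50.877248
50.893384
51.013790
51.018227
51.030214
51.113143
51.140244
51.156136
51.208227
51.392147
51.406583
51.625291
51.638426
51.656370
51.760192
51.773114
51.781975
51.792405
51.991595
52.027901
52.396598
52.411133
52.421011
52.634975
52.647587
52.662538
52.891750
52.901002
53.006275
53.017660
53.127134
53.381442
53.390076
53.401418
53.507574
53.517039
53.626381
53.642249
53.698069
53.702516
53.707477
53.711289
53.715540
53.770560
54.376879
54.626064
54.636148
54.776629
55.006452
55.133931
55.149530
55.159733
55.403834
55.419582
55.431492
55.503828
55.628038
55.639904
55.650147
55.665857
55.750715
55.764251
55.775662
55.783979
55.875768
56.020052
56.034093
56.256160
56.272773
56.288245
56.387302
56.516187
56.642710
56.751920
56.762586
56.881590
57.004702
57.129497
57.138671
57.152728
57.251356
57.261731
57.269768
57.381010
57.396552
57.755153
58.014478
58.022590
58.026778
58.127895
58.145043
58.271508
58.281624
58.305523
58.683053
58.752555
59.007857
59.020660
59.253125
59.262566
59.388265
59.753469
59.770089
59.773433
59.777772
59.888872
59.894226
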