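"x","y"
-6.2666,3.0386
-6.112,2.8323
-5.9517,2.6508
-5.7859,2.4731
-5.6147,2.2964
-5.4382,2.1279
-5.2567,1.9732
-5.0703,1.8114
-4.8792,1.6609
-4.6835,1.5252
-4.4835,1.3762
-4.2793,1.2543
-4.0711,1.1248
-3.8592,0.994
-3.6436,0.8874
-3.4247,0.7724
-3.2025,0.6645
-2.9774,0.5732
-2.7496,0.4873
-2.5191,0.4119
-2.2863,0.3379
-2.0514,0.271
-1.8146,0.215
-1.5761,0.1498
-1.3361,0.1187
-1.0949,0.0762
-0.8526,0.0493
-0.6096,0.0262
-0.366,0.0035
-0.122,-4e-04
0.122,-0.0034
0.366,0.012
0.6096,0.0238
0.8526,0.0452
1.0949,0.0732
1.3361,0.1095
1.5761,0.1618
1.8146,0.203
2.0514,0.2668
2.2863,0.3352
2.5191,0.4131
2.7496,0.4838
2.9774,0.5733
3.2025,0.6624
3.4247,0.7681
3.6436,0.8759
3.8592,0.9991
4.0711,1.1163
4.2793,1.2413
4.4835,1.3791
4.6835,1.513
4.8792,1.6601
5.0703,1.8138
5.2567,1.978
5.4382,2.1363
5.6147,2.3037
5.7859,2.4673
5.9517,2.6558
6.112,2.8391
6.2666,3.0226
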