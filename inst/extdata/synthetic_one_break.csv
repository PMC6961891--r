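year,abundance
1,3000
2,1098.55766954225
3,2790.27054482939
4,1267.79248879308
5,2643.40304389735
6,1436.75945755607
7,2546.7214807323
8,1436.85766670492
9,2488.72020156065
10,1513.00116009751
11,2522.57651327908
12,1506.62914141722
13,27.0881669368364
14,179.99976191236
15,640.197936396183
16,378.456117537859
17,621.529529658683
18,367.211708587295
19,633.348838767844
20,368.015547178879
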