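
Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts
            A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V   A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V
    1 M    -2  -3  -4  -5  -3  -2  -4  -5  -3   1   2  -3   8  -1  -5  -4  -2  -4  -3   0    0   0   0   0   0   0   0   0   0   0   0   0 100   0   0   0   0   0   0   0  4.32     1.00
    2 K    -1   2   0  -1  -4   1   1  -2  -1  -3  -3   4  -2  -4  -2  -1  -1  -4  -3  -3    0  20   0   0   0  10   0   0   0   0   0  50   0   0   0  10  10   0   0   0  1.23     0.95
    3 V     0  -3  -4  -4  -2  -3  -3  -4  -4   2   1  -3   1  -1  -3  -2   0  -4  -2   5    5   0   0   0   0   0   0   0   0  20  15   0   0   0   0   0   5   0   0  55  0.87     0.90

                      K         Lambda
Standard Ungapped    0.1330     0.3179
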