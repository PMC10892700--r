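tbl,i1,i2,i3,i4,score
A,1,1,1,1,1
A,1,1,1,2,2
A,1,1,2,1,2
A,1,1,2,2,2
A,1,1,3,1,2
A,1,1,3,2,3
A,1,1,4,1,3
A,1,1,4,2,3
A,1,2,1,1,2
A,1,2,1,2,2
A,1,2,2,1,2
A,1,2,2,2,2
A,1,2,3,1,3
A,1,2,3,2,3
A,1,2,4,1,3
A,1,2,4,2,3
A,1,3,1,1,2
A,1,3,1,2,3
A,1,3,2,1,3
A,1,3,2,2,3
A,1,3,3,1,3
A,1,3,3,2,3
A,1,3,4,1,4
A,1,3,4,2,4
A,2,1,1,1,2
A,2,1,1,2,3
A,2,1,2,1,3
A,2,1,2,2,3
A,2,1,3,1,3
A,2,1,3,2,4
A,2,1,4,1,4
A,2,1,4,2,4
A,2,2,1,1,3
A,2,2,1,2,3
A,2,2,2,1,3
A,2,2,2,2,3
A,2,2,3,1,3
A,2,2,3,2,4
A,2,2,4,1,4
A,2,2,4,2,4
A,2,3,1,1,3
A,2,3,1,2,4
A,2,3,2,1,4
A,2,3,2,2,4
A,2,3,3,1,4
A,2,3,3,2,4
A,2,3,4,1,5
A,2,3,4,2,5
A,3,1,1,1,3
A,3,1,1,2,3
A,3,1,2,1,4
A,3,1,2,2,4
A,3,1,3,1,4
A,3,1,3,2,4
A,3,1,4,1,5
A,3,1,4,2,5
A,3,2,1,1,3
A,3,2,1,2,4
A,3,2,2,1,4
A,3,2,2,2,4
A,3,2,3,1,4
A,3,2,3,2,4
A,3,2,4,1,5
A,3,2,4,2,5
A,3,3,1,1,4
A,3,3,1,2,4
A,3,3,2,1,4
A,3,3,2,2,4
A,3,3,3,1,4
A,3,3,3,2,5
A,3,3,4,1,5
A,3,3,4,2,5
A,4,1,1,1,4
A,4,1,1,2,4
A,4,1,2,1,4
A,4,1,2,2,4
A,4,1,3,1,4
A,4,1,3,2,5
A,4,1,4,1,5
A,4,1,4,2,5
A,4,2,1,1,4
A,4,2,1,2,4
A,4,2,2,1,4
A,4,2,2,2,4
A,4,2,3,1,4
A,4,2,3,2,5
A,4,2,4,1,5
A,4,2,4,2,5
A,4,3,1,1,4
A,4,3,1,2,4
A,4,3,2,1,4
A,4,3,2,2,5
A,4,3,3,1,5
A,4,3,3,2,5
A,4,3,4,1,6
A,4,3,4,2,6
A,5,1,1,1,5
A,5,1,1,2,5
A,5,1,2,1,5
A,5,1,2,2,5
A,5,1,3,1,5
A,5,1,3,2,6
A,5,1,4,1,6
A,5,1,4,2,7
A,5,2,1,1,5
A,5,2,1,2,6
A,5,2,2,1,6
A,5,2,2,2,6
A,5,2,3,1,6
A,5,2,3,2,7
A,5,2,4,1,7
A,5,2,4,2,7
A,5,3,1,1,6
A,5,3,1,2,6
A,5,3,2,1,6
A,5,3,2,2,7
A,5,3,3,1,7
A,5,3,3,2,7
A,5,3,4,1,7
A,5,3,4,2,8
A,6,1,1,1,7
A,6,1,1,2,7
A,6,1,2,1,7
A,6,1,2,2,7
A,6,1,3,1,7
A,6,1,3,2,8
A,6,1,4,1,8
A,6,1,4,2,9
A,6,2,1,1,8
A,6,2,1,2,8
A,6,2,2,1,8
A,6,2,2,2,8
A,6,2,3,1,8
A,6,2,3,2,9
A,6,2,4,1,9
A,6,2,4,2,9
A,6,3,1,1,9
A,6,3,1,2,9
A,6,3,2,1,9
A,6,3,2,2,9
A,6,3,3,1,9
A,6,3,3,2,9
A,6,3,4,1,9
A,6,3,4,2,9
B,1,1,1,,1
B,1,1,2,,3
B,1,2,1,,2
B,1,2,2,,3
B,1,3,1,,3
B,1,3,2,,4
B,1,4,1,,5
B,1,4,2,,5
B,1,5,1,,6
B,1,5,2,,6
B,1,6,1,,7
B,1,6,2,,7
B,2,1,1,,2
B,2,1,2,,3
B,2,2,1,,2
B,2,2,2,,3
B,2,3,1,,4
B,2,3,2,,5
B,2,4,1,,5
B,2,4,2,,5
B,2,5,1,,6
B,2,5,2,,7
B,2,6,1,,7
B,2,6,2,,7
B,3,1,1,,3
B,3,1,2,,3
B,3,2,1,,3
B,3,2,2,,4
B,3,3,1,,4
B,3,3,2,,5
B,3,4,1,,5
B,3,4,2,,6
B,3,5,1,,6
B,3,5,2,,7
B,3,6,1,,7
B,3,6,2,,7
B,4,1,1,,5
B,4,1,2,,5
B,4,2,1,,5
B,4,2,2,,6
B,4,3,1,,6
B,4,3,2,,7
B,4,4,1,,7
B,4,4,2,,7
B,4,5,1,,7
B,4,5,2,,7
B,4,6,1,,8
B,4,6,2,,8
B,5,1,1,,7
B,5,1,2,,7
B,5,2,1,,7
B,5,2,2,,7
B,5,3,1,,7
B,5,3,2,,8
B,5,4,1,,8
B,5,4,2,,8
B,5,5,1,,8
B,5,5,2,,8
B,5,6,1,,8
B,5,6,2,,8
B,6,1,1,,8
B,6,1,2,,8
B,6,2,1,,8
B,6,2,2,,8
B,6,3,1,,8
B,6,3,2,,8
B,6,4,1,,8
B,6,4,2,,9
B,6,5,1,,9
B,6,5,2,,9
B,6,6,1,,9
B,6,6,2,,9
C,1,1,,,1
C,1,2,,,2
C,1,3,,,3
C,1,4,,,3
C,1,5,,,4
C,1,6,,,5
C,1,7,,,5
C,2,1,,,2
C,2,2,,,2
C,2,3,,,3
C,2,4,,,4
C,2,5,,,4
C,2,6,,,5
C,2,7,,,5
C,3,1,,,3
C,3,2,,,3
C,3,3,,,3
C,3,4,,,4
C,3,5,,,4
C,3,6,,,5
C,3,7,,,6
C,4,1,,,3
C,4,2,,,3
C,4,3,,,3
C,4,4,,,4
C,4,5,,,5
C,4,6,,,6
C,4,7,,,6
C,5,1,,,4
C,5,2,,,4
C,5,3,,,4
C,5,4,,,5
C,5,5,,,6
C,5,6,,,7
C,5,7,,,7
C,6,1,,,4
C,6,2,,,4
C,6,3,,,5
C,6,4,,,6
C,6,5,,,6
C,6,6,,,7
C,6,7,,,7
C,7,1,,,5
C,7,2,,,5
C,7,3,,,6
C,7,4,,,6
C,7,5,,,7
C,7,6,,,7
C,7,7,,,7
C,8,1,,,5
C,8,2,,,5
C,8,3,,,6
C,8,4,,,7
C,8,5,,,7
C,8,6,,,7
C,8,7,,,7
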