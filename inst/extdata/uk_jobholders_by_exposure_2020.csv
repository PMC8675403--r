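frequency,intensity,jobholders
0,0,35729200
1,1,0
1,2,17900
1,3,1587800
2,1,83500
2,2,408800
2,3,2706700
3,1,3037700
3,2,904600
3,3,789000
4,1,0
4,2,0
4,3,884700
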