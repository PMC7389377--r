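id,time,state
1,0,H
1,1,H
1,2,I
1,3,D
2,0,H
2,1,I
2,2,I
3,0,H
3,1,H
3,2,H
3,3,I
4,0,I
4,1,H
4,2,H
5,0,H
5,1,I
5,2,H
5,3,I
5,4,D
6,0,I
6,1,I
6,2,D
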