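>TOY0001.1 M1BP_like
A [  2  1 55  1  2 50  3  1 ]
C [  3  1  1  2 53  2  3  2 ]
G [ 50 55  2  2  2  4 51  3 ]
T [  3  1  0 53  1  2  1 52 ]
>TOY0002.1 BEAF32_like
A [  1 54  2  1 52  1 ]
C [  2  2 53  2  2  3 ]
G [ 52  1  2  2  2  2 ]
T [  3  1  1 53  2 52 ]
>TOY0003.1 Zld_like
A [  1 50  2  2  1 55  2 ]
C [ 54  2  1  3  1  1  2 ]
G [  2  4 54  2 55  1 53 ]
T [  1  2  1 51  1  1  1 ]
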