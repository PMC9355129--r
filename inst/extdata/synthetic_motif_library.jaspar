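>LEF1_LIKE LEF1_LIKE
A  [ 97 1 1 1 1 1 1 1 ]
C  [ 1 97 1 1 1 1 1 1 ]
G  [ 1 1 1 1 1 97 1 1 ]
T  [ 1 1 97 97 97 1 97 97 ]
>NFIX_LIKE NFIX_LIKE
A  [ 1 1 1 1 1 97 1 97 ]
C  [ 1 1 1 1 97 1 97 1 ]
G  [ 1 1 97 97 1 1 1 1 ]
T  [ 97 97 1 1 1 1 1 1 ]
>SOX2_LIKE SOX2_LIKE
A  [ 1 1 48 1 1 1 1 1 ]
C  [ 97 97 2 1 1 1 1 1 ]
G  [ 1 1 2 1 1 97 1 1 ]
T  [ 1 1 48 97 97 1 97 97 ]
>ASCL1_LIKE ASCL1_LIKE
A  [ 97 1 1 97 1 1 1 1 ]
C  [ 1 1 97 1 1 97 1 1 ]
G  [ 1 97 1 1 97 1 1 97 ]
T  [ 1 1 1 1 1 1 97 1 ]
>ASCL2_LIKE ASCL2_LIKE
A  [ 1 97 1 1 1 1 1 97 ]
C  [ 97 1 1 97 1 1 97 1 ]
G  [ 1 1 97 1 1 97 1 1 ]
T  [ 1 1 1 1 97 1 1 1 ]
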