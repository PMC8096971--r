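>NKX
A: 0.05 0.05 0.85 0.85 0.05 0.05 0.05 0.05
C: 0.05 0.85 0.05 0.05 0.05 0.05 0.05 0.85
G: 0.05 0.05 0.05 0.05 0.85 0.05 0.85 0.05
T: 0.85 0.05 0.05 0.05 0.05 0.85 0.05 0.05
>TEAD
A: 0.05 0.85 0.05 0.85 0.05 0.05 0.05 0.05 0.85 0.05
C: 0.05 0.05 0.85 0.05 0.05 0.05 0.85 0.85 0.05 0.85
G: 0.85 0.05 0.05 0.05 0.05 0.05 0.05 0.05 0.05 0.05
T: 0.05 0.05 0.05 0.05 0.85 0.85 0.05 0.05 0.05 0.05
>CEBP
A: 0.05 0.05 0.05 0.05 0.05 0.05 0.85 0.85
C: 0.05 0.05 0.05 0.85 0.05 0.85 0.05 0.05
G: 0.05 0.05 0.85 0.05 0.85 0.05 0.05 0.05
T: 0.85 0.85 0.05 0.05 0.05 0.05 0.05 0.05
>CTCF
A: 0.05 0.05 0.85 0.05 0.05 0.85 0.05 0.05 0.05 0.05 0.05 0.05
C: 0.85 0.85 0.05 0.85 0.85 0.05 0.05 0.05 0.05 0.05 0.05 0.85
G: 0.05 0.05 0.05 0.05 0.05 0.05 0.85 0.85 0.85 0.85 0.85 0.05
T: 0.05 0.05 0.05 0.05 0.05 0.05 0.05 0.05 0.05 0.05 0.05 0.05
>FOXA
A: 0.05 0.05 0.05 0.05 0.05 0.85 0.05 0.05
C: 0.05 0.05 0.05 0.05 0.05 0.05 0.85 0.05
G: 0.05 0.85 0.05 0.05 0.05 0.05 0.05 0.05
T: 0.85 0.05 0.85 0.85 0.85 0.05 0.05 0.85
>AP1
A: 0.05 0.05 0.85 0.05 0.05 0.05 0.85
C: 0.05 0.05 0.05 0.85 0.05 0.85 0.05
G: 0.05 0.85 0.05 0.05 0.05 0.05 0.05
T: 0.85 0.05 0.05 0.05 0.85 0.05 0.05
>ELF
A: 0.85 0.05 0.05 0.05 0.05 0.85 0.85 0.05 0.05
C: 0.05 0.85 0.85 0.05 0.05 0.05 0.05 0.05 0.05
G: 0.05 0.05 0.05 0.85 0.85 0.05 0.05 0.85 0.05
T: 0.05 0.05 0.05 0.05 0.05 0.05 0.05 0.05 0.85
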