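# Random-coil 1H chemical shifts (ppm) for unstructured peptides.
# Hand-entered reference values following the standard random-coil
# compilations of Wishart and co-workers (rounded to 0.01 ppm); intended as
# an editable default -- substitute your own table via the `reference`
# argument of random_coil_deviation() if you use a different compilation.
# Columns: one-letter residue code, proton name, shift in ppm.
code,atom,ppm
A,HN,8.24
A,HA,4.32
A,HB,1.39
R,HN,8.23
R,HA,4.34
R,HB,1.79
R,HG,1.63
D,HN,8.34
D,HA,4.64
D,HB,2.72
E,HN,8.42
E,HA,4.35
E,HB,2.01
E,HG,2.31
Q,HN,8.32
Q,HA,4.34
Q,HB,2.05
Q,HG,2.32
I,HN,8.00
I,HA,4.17
I,HB,1.87
I,HG,1.27
K,HN,8.29
K,HA,4.32
K,HB,1.78
K,HG,1.37
L,HN,8.16
L,HA,4.34
L,HB,1.62
L,HG,1.59
S,HN,8.31
S,HA,4.47
S,HB,3.87
T,HN,8.15
T,HA,4.35
T,HB,4.22
T,HG,1.21
V,HN,8.03
V,HA,4.12
V,HB,2.08
V,HG,0.93
G,HN,8.33
G,HA,3.96
N,HN,8.40
N,HA,4.74
N,HB,2.80
M,HN,8.28
M,HA,4.48
M,HB,2.02
M,HG,2.56
F,HN,8.30
F,HA,4.62
F,HB,3.10
H,HN,8.42
H,HA,4.63
H,HB,3.20
W,HN,8.25
W,HA,4.66
W,HB,3.25
Y,HN,8.12
Y,HA,4.55
Y,HB,2.98
C,HN,8.32
C,HA,4.55
C,HB,2.95
P,HA,4.42
P,HB,2.05
P,HG,1.95
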