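ATOM      1  N9  DG  A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  C8  DG  A   1       1.370   0.060   0.000  1.00  0.00           C
ATOM      3  N7  DG  A   1       2.020  -1.080   0.000  1.00  0.00           N
ATOM      4  C5  DG  A   1       1.120  -2.080   0.000  1.00  0.00           C
ATOM      5  C6  DG  A   1       1.290  -3.470   0.000  1.00  0.00           C
ATOM      6  O6  DG  A   1       2.350  -4.080   0.000  1.00  0.00           O
ATOM      7  N1  DG  A   1       0.110  -4.160   0.000  1.00  0.00           N
ATOM      8  C2  DG  A   1      -1.110  -3.590   0.000  1.00  0.00           C
ATOM      9  N2  DG  A   1      -2.190  -4.370   0.000  1.00  0.00           N
ATOM     10  N3  DG  A   1      -1.290  -2.280   0.000  1.00  0.00           N
ATOM     11  C4  DG  A   1      -0.140  -1.540   0.000  1.00  0.00           C
ATOM     12  H8  DG  A   1       1.840   1.030   0.000  1.00  0.00           H
ATOM     13  H1  DG  A   1       0.150  -5.160   0.000  1.00  0.00           H
ATOM     14  H21 DG  A   1      -3.080  -3.940   0.000  1.00  0.00           H
ATOM     15  H22 DG  A   1      -2.090  -5.370   0.000  1.00  0.00           H
ATOM     16  C1' DG  A   1      -0.760   1.200   0.550  1.00  0.00           C
ATOM     17  O4' DG  A   1      -2.100   1.050   0.300  1.00  0.00           O
ATOM     18  C2' DG  A   1      -0.400   2.480  -0.200  1.00  0.00           C
ATOM     19  C3' DG  A   1      -1.650   3.340   0.000  1.00  0.00           C
ATOM     20  O3' DG  A   1      -1.700   4.400  -0.930  1.00  0.00           O
ATOM     21  C4' DG  A   1      -2.800   2.350  -0.200  1.00  0.00           C
ATOM     22  C5' DG  A   1      -3.900   2.500   0.830  1.00  0.00           C
ATOM     23  O5' DG  A   1      -5.000   1.650   0.500  1.00  0.00           O
ATOM     24  P   DG  A   1      -6.300   1.700   1.400  1.00  0.00           P
ATOM     25  OP1 DG  A   1      -7.300   0.800   0.800  1.00  0.00           O
ATOM     26  OP2 DG  A   1      -6.100   1.400   2.840  1.00  0.00           O
ATOM     27  H1' DG  A   1      -0.600   1.300   1.630  1.00  0.00           H
ATOM     28  H2' DG  A   1       0.560   2.900   0.100  1.00  0.00           H
ATOM     29 H2'' DG  A   1      -0.350   2.300  -1.280  1.00  0.00           H
ATOM     30  H3' DG  A   1      -1.700   3.750   1.010  1.00  0.00           H
ATOM     31  H4' DG  A   1      -3.200   2.400  -1.210  1.00  0.00           H
ATOM     32  H5' DG  A   1      -4.250   3.540   0.830  1.00  0.00           H
ATOM     33 H5'' DG  A   1      -3.550   2.250   1.840  1.00  0.00           H
END
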