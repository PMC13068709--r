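REMARK  synthetic probe profile (bound state) for examples and tests
REMARK  coarse-grained charge beads, not a measured structure; the
REMARK  elongated z-coordinates and extra target bead emulate a
REMARK  binding-induced conformational change
ATOM      1  P1  PRB     1      0.000   0.000  16.000  -1.000   2.000
ATOM      2  P2  PRB     1      3.000   1.000  40.000  -1.000   2.000
ATOM      3  P3  PRB     1     -2.000   2.000  64.000  -1.000   2.000
ATOM      4  P4  PRB     1      1.000  -2.000  88.000  -1.000   2.000
ATOM      5  P5  PRB     1      0.000   1.000 112.000  -1.000   2.000
HETATM    6  T1  TGT     1      2.000   0.000 120.000  -0.500   4.000
END
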