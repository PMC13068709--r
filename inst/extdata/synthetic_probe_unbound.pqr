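REMARK  synthetic probe profile (unbound state) for examples and tests
REMARK  coarse-grained charge beads, not a measured structure
REMARK  coordinates in angstrom, charges in e, radii in angstrom
ATOM      1  P1  PRB     1      0.000   0.000  12.000  -1.000   2.000
ATOM      2  P2  PRB     1      3.000   1.000  30.000  -1.000   2.000
ATOM      3  P3  PRB     1     -2.000   2.000  48.000  -1.000   2.000
ATOM      4  P4  PRB     1      1.000  -2.000  66.000  -1.000   2.000
ATOM      5  P5  PRB     1      0.000   1.000  84.000  -1.000   2.000
ATOM      6  B1  PRB     1      2.000   0.000  95.000   0.000   3.000
END
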