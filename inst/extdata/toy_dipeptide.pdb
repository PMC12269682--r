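ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N  
ATOM      2  CA  ALA A   1       1.460   0.000   0.000  1.00  0.00           C  
ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C  
ATOM      4  O   ALA A   1       1.300   2.400   0.000  1.00  0.00           O  
ATOM      5  CB  ALA A   1       2.000  -1.200   1.000  1.00  0.00           C  
ATOM      6  N   SER A   2       3.330   1.500   0.000  1.00  0.00           N  
ATOM      7  CA  SER A   2       4.000   2.800   0.000  1.00  0.00           C  
ATOM      8  C   SER A   2       5.500   2.700   0.000  1.00  0.00           C  
ATOM      9  O   SER A   2       6.100   1.600   0.000  1.00  0.00           O  
ATOM     10  OG  SER A   2       3.600   3.600   1.200  1.00  0.00           O  
END   
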