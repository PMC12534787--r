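ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N  
ATOM      2  CA  ALA A   1       1.500   0.400   0.000  1.00  0.00           C  
ATOM      3  C   ALA A   1       2.200   1.600   0.000  1.00  0.00           C  
ATOM      4  O   ALA A   1       3.100   1.700   0.000  1.00  0.00           O  
ATOM      5  CA  GLY A   2       4.000   2.000   0.000  1.00  0.00           C  
ATOM      6  C   GLY A   2       5.500   2.300   0.000  1.00  0.00           C  
ATOM      7  O   GLY A   2       6.200   3.400   0.000  1.00  0.00           O  
ATOM      8  N   PHE A   3       7.000   3.500   0.000  1.00  0.00           N  
ATOM      9  CA  PHE A   3       8.500   3.800   0.000  1.00  0.00           C  
ATOM     10  C   PHE A   3       9.300   5.000   0.000  1.00  0.00           C  
HETATM   11  C1  HEM A   9      12.000   0.500   0.000  1.00  0.00           C  
HETATM   12  C2  HEM A   9      13.000   0.500   0.000  1.00  0.00           C  
HETATM   13  C3  HEM A   9      12.000   1.500   0.000  1.00  0.00           C  
HETATM   14 C4   HEM A   9      13.000   1.500   0.000  1.00  0.00          FE  
END   
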