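ATOM      1  CA  GLU A   1       0.000   0.740   0.000  1.00  0.00           C  
ATOM      2  CA  HIS A   2       3.500  -0.740   0.000  1.00  0.00           C  
ATOM      3  CA  ALA A   3       7.000   0.740   0.000  1.00  0.00           C  
ATOM      4  CA  CYS A   4      10.500  -0.740   0.000  1.00  0.00           C  
ATOM      5  CA  MET A   5      14.000   0.740   0.000  1.00  0.00           C  
ATOM      6  CA  GLN A   6      17.500  -0.740   0.000  1.00  0.00           C  
ATOM      7  CA  VAL A   7      21.000   0.740   0.000  1.00  0.00           C  
ATOM      8  CA  TRP A   8      24.500  -0.740   0.000  1.00  0.00           C  
ATOM      9  CA  ALA A   9      28.000   0.740   0.000  1.00  0.00           C  
ATOM     10  CA  LEU A  10      31.500  -0.740   0.000  1.00  0.00           C  
ATOM     11  CA  GLN A  11      35.000   0.740   0.000  1.00  0.00           C  
ATOM     12  CA  LEU A  12      38.500  -0.740   0.000  1.00  0.00           C  
ATOM     13  CA  HIS A  13      42.000   0.740   0.000  1.00  0.00           C  
ATOM     14  CA  LYS A  14      45.500  -0.740   0.000  1.00  0.00           C  
ATOM     15  CA  ARG A  15      49.000   0.740   0.000  1.00  0.00           C  
ATOM     16  CA  PHE A  16      52.500  -0.740   0.000  1.00  0.00           C  
ATOM     17  CA  LYS A  17      51.303   0.740  -3.289  1.00  0.00           C  
ATOM     18  CA  GLN A  18      50.106  -0.740  -6.578  1.00  0.00           C  
ATOM     19  CA  PHE A  19      48.909   0.740  -9.867  1.00  0.00           C  
ATOM     20  CA  PHE A  20      47.712  -0.740 -13.156  1.00  0.00           C  
ATOM     21  CA  CYS A  21      46.515   0.740 -16.445  1.00  0.00           C  
ATOM     22  CA  LEU A  22      45.318  -0.740 -19.734  1.00  0.00           C  
ATOM     23  CA  ASN A  23      44.121   0.740 -23.022  1.00  0.00           C  
ATOM     24  CA  ARG A  24      42.923  -0.740 -26.311  1.00  0.00           C  
ATOM     25  CA  ALA A  25      41.726   0.740 -29.600  1.00  0.00           C  
ATOM     26  CA  TYR A  26      40.529  -0.740 -32.889  1.00  0.00           C  
ATOM     27  CA  ASP A  27      39.332   0.740 -36.178  1.00  0.00           C  
ATOM     28  CA  GLY A  28      38.135  -0.740 -39.467  1.00  0.00           C  
ATOM     29  CA  LEU A  29      36.938   0.740 -42.756  1.00  0.00           C  
ATOM     30  CA  LEU A  30      35.741  -0.740 -46.045  1.00  0.00           C  
ATOM     31  CA  GLY A  31      34.544   0.740 -49.334  1.00  0.00           C  
ATOM     32  CA  ARG A  32      33.347  -0.740 -52.623  1.00  0.00           C  
END
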