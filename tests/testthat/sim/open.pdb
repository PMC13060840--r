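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
ATOM     17  CA  LYS A  17      55.947   0.740  -0.608  1.00  0.00           C  
ATOM     18  CA  GLN A  18      59.394  -0.740  -1.216  1.00  0.00           C  
ATOM     19  CA  PHE A  19      62.840   0.740  -1.823  1.00  0.00           C  
ATOM     20  CA  PHE A  20      66.287  -0.740  -2.431  1.00  0.00           C  
ATOM     21  CA  CYS A  21      69.734   0.740  -3.039  1.00  0.00           C  
ATOM     22  CA  LEU A  22      73.181  -0.740  -3.647  1.00  0.00           C  
ATOM     23  CA  ASN A  23      76.628   0.740  -4.254  1.00  0.00           C  
ATOM     24  CA  ARG A  24      80.075  -0.740  -4.862  1.00  0.00           C  
ATOM     25  CA  ALA A  25      83.521   0.740  -5.470  1.00  0.00           C  
ATOM     26  CA  TYR A  26      86.968  -0.740  -6.078  1.00  0.00           C  
ATOM     27  CA  ASP A  27      90.415   0.740  -6.685  1.00  0.00           C  
ATOM     28  CA  GLY A  28      93.862  -0.740  -7.293  1.00  0.00           C  
ATOM     29  CA  LEU A  29      97.309   0.740  -7.901  1.00  0.00           C  
ATOM     30  CA  LEU A  30     100.756  -0.740  -8.509  1.00  0.00           C  
ATOM     31  CA  GLY A  31     104.202   0.740  -9.117  1.00  0.00           C  
ATOM     32  CA  ARG A  32     107.649  -0.740  -9.724  1.00  0.00           C  
END
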