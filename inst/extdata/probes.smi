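CCO ethanol
CC(C)O isopropanol
CC(C)CO isobutanol
CC(C)=O acetone
CC=O acetaldehyde
CC(N)=O acetamide
CNC(C)=O n_methylacetamide
CC(=O)O acetic_acid
CN methylamine
NC(N)=O urea
CC#N acetonitrile
COC dimethyl_ether
c1ccccc1 benzene
Oc1ccccc1 phenol
C1CCCCC1 cyclohexane
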