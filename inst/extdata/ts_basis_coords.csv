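kind,label,value_aug_cc_pvdz,value_6311gss,source
bond,N7-C8,1.358,1.336,"transition state bond length, solution phase, DFT/B3LYP"
bond,C8-O10,1.363,1.344,"transition state bond length, solution phase, DFT/B3LYP"
bond,C8-N9,2.014,2.103,"transition state breaking-bond length, solution phase, DFT/B3LYP"
bond,N9-C4,1.312,1.293,"transition state bond length, solution phase, DFT/B3LYP"
angle,N7-C8-O10,112.6,114.4,"transition state bending angle, solution phase, DFT/B3LYP"
angle,N9-C8-O10,123.7,121.3,"transition state bending angle, solution phase, DFT/B3LYP"
angle,C8-O10-H10,106.2,106.9,"transition state bending angle, solution phase, DFT/B3LYP"
dihedral,C5-N7-C8-O10,-134.1,-132.3,"transition state torsion, solution phase, DFT/B3LYP"
dihedral,C5-N7-C8-H8,86.1,78.6,"transition state torsion, solution phase, DFT/B3LYP"
dihedral,N7-C8-O10-H10,8.5,7.8,"transition state torsion, solution phase, DFT/B3LYP"
dihedral,C8-H8-N9-H9,-145.5,-147.1,"transition state torsion, solution phase, DFT/B3LYP"
dihedral,C8-H8-O10-H10,-34.1,-25.1,"transition state torsion, solution phase, DFT/B3LYP"
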