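state,kind,label,value_gas,value_solution,source
reactant,bond,C8-O10,1.411,1.432,"hydroxyl-to-C8 distance at the reactant complex"
reactant,angle,N7-C8-O10,112.8,107.9,"reactant complex bending angle"
reactant,angle,N7-C8-H8,111.5,113.6,"reactant complex bending angle"
reactant,angle,H8-C8-N9,109.6,111.1,"reactant complex bending angle"
reactant,dihedral,C5-N7-C8-O10,-123.4,-115.8,"reactant complex torsion"
reactant,dihedral,C5-N7-C8-H8,118.1,127.7,"reactant complex torsion"
reactant,dihedral,C8-H8-N9-H9,-130.1,-138.9,"reactant complex torsion"
ts,angle,N7-C8-O10,115.7,114.4,"transition state bending angle"
ts,angle,N9-C8-H8,80.5,83.4,"transition state bending angle"
ts,angle,C8-O10-H10,103.9,106.9,"transition state bending angle"
ts,dihedral,C5-N7-C8-O10,-136.5,-132.3,"transition state torsion"
ts,dihedral,C5-N7-C8-H8,67.6,78.6,"transition state torsion"
ts,dihedral,N7-C8-O10-H10,5.2,7.8,"transition state torsion"
ts,dihedral,C8-H8-O10-H10,-20.2,-25.1,"transition state torsion"
product,bond,C8-N9,2.802,2.812,"broken-bond distance at the product complex"
product,angle,N9-C8-H8,55.4,53.5,"product complex bending angle"
product,angle,C8-O10-H10,107.5,109.7,"product complex bending angle"
product,dihedral,C5-N7-C8-O10,-170.4,-163.2,"product complex torsion"
product,dihedral,C5-N7-C8-H8,11.6,19.0,"product complex torsion"
product,dihedral,C8-H8-N9-H9,-170.1,-146.9,"product complex torsion"
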