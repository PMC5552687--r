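quantity,value,unit,source
gas_barrier_high,19.2,kcal/mol,"gas-phase barrier height, coupled-cluster tier"
gas_reaction_high,7.6,kcal/mol,"gas-phase reaction energy, coupled-cluster tier"
gas_barrier_low,17.3,kcal/mol,"gas-phase barrier height, DFT tier"
pmf_barrier_low,28.8,kcal/mol,"solution PMF barrier, DFT/MM tier"
pmf_barrier_high,31.6,kcal/mol,"solution PMF barrier, coupled-cluster/MM tier"
pmf_reaction_low,13.7,kcal/mol,"solution PMF reaction energy, DFT/MM tier"
pmf_reaction_high,15.9,kcal/mol,"solution PMF reaction energy, coupled-cluster/MM tier"
solvent_energy_barrier,6.0,kcal/mol,"solvent-energy contribution to the barrier height"
solvent_energy_reaction,27.9,kcal/mol,"solvent-energy contribution to the reaction energy"
polarization_reactant,9.4,kcal/mol,"polarization contribution at the reactant state"
polarization_ts,8.7,kcal/mol,"polarization contribution at the transition state"
polarization_product,8.6,kcal/mol,"polarization contribution at the product state"
aqueous_barrier,5.3,kcal/mol,"net aqueous contribution to the barrier height"
aqueous_reaction,27.1,kcal/mol,"net aqueous contribution to the reaction energy"
gsolv_reactant,-25.2,kcal/mol,"solvation free energy of the reactant complex (continuum input)"
gsolv_ts,-17.3,kcal/mol,"solvation free energy of the transition state (continuum input)"
gsolv_product,-17.3,kcal/mol,"solvation free energy of the product complex (continuum input)"
estimated_solution_barrier,27.1,kcal/mol,"solution barrier estimated from the gas profile and solvation cycle"
estimated_solution_reaction,15.5,kcal/mol,"solution reaction energy estimated from the gas profile and solvation cycle"
imag_freq_gas,236.2,1/cm,"imaginary frequency magnitude of the gas-phase transition state"
imag_freq_solution,280.9,1/cm,"imaginary frequency magnitude of the solution-phase transition state"
hbond_mean_ts_aug,2.777,A,"mean weak hydrogen-bond distance at the transition state, larger basis"
hbond_mean_ts_6311,2.572,A,"mean weak hydrogen-bond distance at the transition state, smaller basis"
hbond_strong_reactant,1.766,A,"strong hydrogen bond at the solution reactant complex"
bond_break_reactant,1.466,A,"breakable C8-N9 bond length at the solution reactant complex"
bond_break_product,2.812,A,"broken C8-N9 distance at the solution product complex"
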