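species,final_energy_kJ_mol,solvation_energy_kJ_mol,dipole_D
chondroitin_sulfate,-58.02,-183.86,4.190
proteinoid,-6.21,-163.01,9.212
cs_proteinoid_complex,-137.18,-326.25,18.880
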