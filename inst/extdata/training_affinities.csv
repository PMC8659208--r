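system,ligand,kd_micromolar,docking_score,unit
4UIW,1,0.002,-9.0,kcal/mol
5F1H,5,0.014,-9.2,kcal/mol
5IGM,6,0.042,-6.7,kcal/mol
5E9V,4,0.070,-4.8,kcal/mol
6V14,8,0.082,-8.3,kcal/mol
4XY8,2,0.397,-9.3,kcal/mol
4Z6I,3,0.493,-7.9,kcal/mol
6V0S,7,16,-4.5,kcal/mol
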