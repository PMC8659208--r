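system,replica,value,unit
apo,1,2.53,angstrom
apo,2,3.45,angstrom
apo,3,2.40,angstrom
4UIW,1,2.07,angstrom
4UIW,2,2.56,angstrom
4UIW,3,1.89,angstrom
4XY8,1,4.25,angstrom
4XY8,2,3.73,angstrom
4XY8,3,4.17,angstrom
4Z6I,1,2.75,angstrom
4Z6I,2,2.63,angstrom
4Z6I,3,3.44,angstrom
5E9V,1,3.12,angstrom
5E9V,2,2.67,angstrom
5E9V,3,3.16,angstrom
5F1H,1,1.94,angstrom
5F1H,2,1.82,angstrom
5F1H,3,2.87,angstrom
5IGM,1,2.77,angstrom
5IGM,2,2.41,angstrom
5IGM,3,2.48,angstrom
6V0S,1,1.83,angstrom
6V0S,2,3.02,angstrom
6V0S,3,3.39,angstrom
6V14,1,2.41,angstrom
6V14,2,1.87,angstrom
6V14,3,2.12,angstrom
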