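system,replica,value,unit
4UIW,1,-81.7,kcal/mol
4UIW,2,-85.3,kcal/mol
4UIW,3,-96.4,kcal/mol
5F1H,1,-75.7,kcal/mol
5F1H,2,-75.7,kcal/mol
5F1H,3,-72.4,kcal/mol
5IGM,1,-71.1,kcal/mol
5IGM,2,-71.1,kcal/mol
5IGM,3,-71.1,kcal/mol
5E9V,1,-51.5,kcal/mol
5E9V,2,-47.7,kcal/mol
5E9V,3,-52.2,kcal/mol
6V14,1,-69.1,kcal/mol
6V14,2,-64.4,kcal/mol
6V14,3,-64.0,kcal/mol
4XY8,1,-43.5,kcal/mol
4XY8,2,-51.3,kcal/mol
4XY8,3,-39.3,kcal/mol
4Z6I,1,-54.2,kcal/mol
4Z6I,2,-78.5,kcal/mol
4Z6I,3,-76.9,kcal/mol
6V0S,1,-25.6,kcal/mol
6V0S,2,-45.6,kcal/mol
6V0S,3,-43.4,kcal/mol
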