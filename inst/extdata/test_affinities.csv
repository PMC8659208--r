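system,kd_micromolar,docking_score,mmgbsa,unit
9,0.0094,-9.4,-78.88,kcal/mol
10a,0.099,-5.3,-52.01,kcal/mol
10b,0.099,-5.2,-70.70,kcal/mol
11,1.01,-7.4,-70.41,kcal/mol
12,17.0,-5.9,-76.08,kcal/mol
13,NA,-5.7,-58.69,kcal/mol
14,NA,-7.9,-64.27,kcal/mol
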