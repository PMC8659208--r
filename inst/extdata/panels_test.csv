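system,docking_score,docking_contacts,mmgbsa,site_energy,total_energy,md_contacts,rmsd_mean,rmsf_violations,rg_width,published_label
9,-9.4,8,-78.88,-17.67,-61.60,4,2.97,0,0.69,Excellent
10a,-5.3,7,-52.01,-5.88,-13.00,0,3.25,0,0.90,Bad
10b,-3.8,6,-70.70,-17.36,-17.36,3,2.19,0,0.75,Good
11,-7.4,7,-70.41,-13.66,-13.66,3,3.35,0,1.00,Intermediate
12,-5.9,9,-76.08,-15.37,-29.07,4,3.23,1,0.86,Good
13,-5.7,8,-58.69,-12.03,-17.96,2,3.32,0,0.94,Bad
14,-7.9,8,-64.27,-18.56,-18.56,3,3.15,2,1.01,Bad
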