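system,docking_score,docking_contacts,mmgbsa,site_energy,total_energy,md_contacts,rmsd_mean,rmsf_violations,rg_width,published_label
4UIW,-7.6,8,-87.80,-29.13,-62.96,5,2.17,0,0.70,Excellent
5F1H,-9.2,7,-74.73,-15.20,-56.43,3,2.21,0,0.47,Good
5IGM,-6.7,7,-71.09,-20.48,-20.48,3,2.55,0,0.63,Good
5E9V,-4.8,7,-50.44,1.61,-32.19,0,2.98,0,1.27,Intermediate
6V14,-8.3,7,-65.86,-20.57,-20.57,2,2.13,0,0.72,Intermediate
4XY8,-9.3,7,-44.67,0.00,0.00,1,4.05,1,1.15,Bad
4Z6I,-7.9,8,-69.85,-13.99,-13.99,2,2.94,2,0.66,Intermediate
6V0S,-4.5,7,-38.17,5.55,-12.45,1,2.74,0,0.58,Bad
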