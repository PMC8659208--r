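# BRD9 binding-site definition.
target_name: BRD9
# Pocket residues monitored for apo-resemblance and structural descriptors.
pocket_residues:
  - Gly43
  - Phe44
  - Phe45
  - Phe47
  - Pro48
  - Val49
  - Ile53
  - Ala54
  - Pro55
  - Tyr57
  - Met92
  - Asn95
  - Ala96
  - Met97
  - Tyr99
  - Asn100
  - Arg101
  - Thr104
  - Tyr106
# Residues regarded as crucial for ligand binding; carried verbatim
# (Ala46 belongs here although it is not in the pocket list above).
key_residues:
  - Phe44
  - Phe45
  - Ala46
  - Val49
  - Ile53
  - Tyr99
  - Asn100
  - Arg101
  - Tyr106
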