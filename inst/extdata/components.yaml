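# Chemical-component codes accepted per role. Edit and load with
# read_config() to track changes in the PDB chemical dictionary.
components:
  ntp: [ATP, GTP]
  ntp_analog: [ANP, GNP, ACP, GCP, AGS, GSP]
  ndp: [ADP, GDP]
  mimic: [ALF, AF3, MGF, BEF, VO4, PO4, PI]
  ion: [MG, MN, CA]
  water: [HOH, WAT, DOD]
resolution_max: 2.5
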