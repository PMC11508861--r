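# Default score definitions: the 13-SNP lipid panel split into the three
# unweighted allele-count scores. The TG score also counts the APOE
# epsilon2 haplotype dosage (include_apoe_e2 defaults to true for TG).
LDL:
  members: [rs12916, rs1529729, rs599839, rs429358, rs7412]
HDL:
  members: [rs301, rs3916027, rs17231506, rs708272]
TG:
  members: [rs1260326, rs17145713, rs3916027, rs328, rs17108993]
  include_apoe_e2: true
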