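# Default class-specific regional hypometabolism profiles, version 1.
#
# Each delta is the fractional intensity reduction applied inside the named
# atlas region (0 = no change, 1 = complete signal loss). CN carries no
# deltas; MCI is derived as mci_lambda times the AD profile, modelling an
# intermediate CN -> MCI -> AD phenotype.
version: 1
mci_lambda: 0.5
effects:
  AD:
    posterior_cingulate: 0.40
  DLB:
    posterior_cingulate: 0.30
    occipital: 0.35
  FTLD:
    frontal: 0.35
    temporal: 0.35
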