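# Feature records for the posture discriminant, as printed: this model's
# values and the earlier alternative reconstruction's.
records:
  - taxon: Riojasuchus_this_model
    mass_kg: 24.56
    com_craniad_m: 0.0986
    ga_m: 0.355
    forelimb_m: 0.222
    hindlimb_m: 0.320
  - taxon: Riojasuchus_alternative
    mass_kg: 13.55
    com_craniad_m: 0.1364
    ga_m: 0.400
    forelimb_m: 0.222
    hindlimb_m: 0.420
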