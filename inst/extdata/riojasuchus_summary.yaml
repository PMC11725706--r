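# Published whole-body summary measurements for the Riojasuchus model
# (meters, kilograms, degrees), plus the earlier alternative model's values
# used in the posture re-analysis.
taxon: Riojasuchus tenuisceps
units: {length: m, mass: kg, angle: deg, circumference: mm}
model:
  body_mass_kg: 24.56
  ga_m: 0.355                 # gleno-acetabular distance
  hindlimb_m: 0.320
  forelimb_m: 0.222
  femur_m: 0.179
  com_craniad_m: 0.0986       # from the acetabula, "realistic" pose
  com_ventrad_m: 0.0594
  foot_support_craniad_m: 0.11  # feet extended > 0.11 m craniad of acetabula
allometric:
  c_humerus_mm: 39
  c_femur_mm: 66
  mass_kg: 28.33
  prediction_error: 0.256
alternative_model:           # earlier published whole-body reconstruction
  body_mass_kg: 13.55
  ga_m: 0.400
  hindlimb_m: 0.420
  forelimb_m: 0.222
  com_craniad_m: 0.1364
realistic_pose:              # degrees of flexion adjustments
  hip: {z: -10}
  knee: {z: -10}
  ankle: {z: -10}
  elbow: {z: -10}
  shoulder: {z: 10}
  wrist: {z: 10}
lda_vote:
  bipedal_votes: 12
  n_training_sets: 22
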