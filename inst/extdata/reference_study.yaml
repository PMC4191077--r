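# Reference seven-arm study design: 4 g Hb bolus over 10 min, optional 4 g Hp
# over the following 10 min; glucocorticoid pre-treatment emulated as elevated
# basal Hp. Loaded with load_study_arms(); equivalent to
# reference_study_arms(seed = 20140385).
dog_hb:
  hb_dose_g: 4
  basal_hp_uM: 90
  complex_clearance_mode: first_order
  n_subjects: 4
  seed: 20140385
  phenotype: dog
  analytes: [total_hb]
human_hb:
  hb_dose_g: 4
  basal_hp_uM: 90
  complex_clearance_mode: first_order
  n_subjects: 4
  seed: 20140485
  phenotype: dog
  analytes: [total_hb]
prednisone_dog_hb:
  hb_dose_g: 4
  basal_hp_uM: 280
  complex_clearance_mode: first_order
  n_subjects: 6
  seed: 20140585
  phenotype: dog
  analytes: [free_hb, bound_hb]
prednisone_human_hb:
  hb_dose_g: 4
  basal_hp_uM: 280
  complex_clearance_mode: first_order
  n_subjects: 6
  seed: 20140685
  phenotype: dog
  analytes: [free_hb, bound_hb]
human_hb_dimeric_hp:
  hb_dose_g: 4
  hp_dose_g: 4
  basal_hp_uM: 90
  complex_clearance_mode: michaelis_menten
  n_subjects: 6
  seed: 20140785
  phenotype: human_dimeric
  analytes: [free_hb, bound_hb]
human_hb_multimeric_hp:
  hb_dose_g: 4
  hp_dose_g: 4
  basal_hp_uM: 90
  complex_clearance_mode: michaelis_menten
  n_subjects: 6
  seed: 20140885
  phenotype: human_multimeric
  analytes: [free_hb, bound_hb]
prednisone_human_hb_multimeric_hp:
  hb_dose_g: 4
  hp_dose_g: 4
  basal_hp_uM: 280
  complex_clearance_mode: michaelis_menten
  n_subjects: 6
  seed: 20140985
  phenotype: human_multimeric
  analytes: [free_hb, bound_hb]
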