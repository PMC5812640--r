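patient_id: ID
covariates:
  age_y: Age
  sex: Sex
  rt_type: RT type
  gd_vials: Gd vials
  interval_months: Interval mo
  egfr: eGFR
  hepatic_function: Hepatic
  tmz_timing: TMZ timing
regions:
  peritumoral:
    pre: peritumoral pre R1
    post: peritumoral post R1
    final: Peritumoral final R1
    dose_class: high
  thalamus_right:
    pre: thalamus right pre R1
    post: thalamus right post R1
    dose_class_column: thalamus right dose class
  thalamus_left:
    pre: thalamus left pre R1
    post: thalamus left post R1
    dose_class_column: thalamus left dose class
  gp_right:
    pre: gp right pre R1
    post: gp right post R1
    dose_class_column: gp right dose class
  gp_left:
    pre: gp left pre R1
    post: gp left post R1
    dose_class_column: gp left dose class
  frontal_wm_right:
    pre: frontal wm right pre R1
    post: frontal wm right post R1
    dose_class_column: frontal wm right dose class
  frontal_wm_left:
    pre: frontal wm left pre R1
    post: frontal wm left post R1
    dose_class_column: frontal wm left dose class
  parietal_wm_right:
    pre: parietal wm right pre R1
    post: parietal wm right post R1
    dose_class_column: parietal wm right dose class
  parietal_wm_left:
    pre: parietal wm left pre R1
    post: parietal wm left post R1
    dose_class_column: parietal wm left dose class
  temporal_wm_right:
    pre: temporal wm right pre R1
    post: temporal wm right post R1
    dose_class_column: temporal wm right dose class
  temporal_wm_left:
    pre: temporal wm left pre R1
    post: temporal wm left post R1
    dose_class_column: temporal wm left dose class
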