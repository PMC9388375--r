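# Blood-pressure risk and treatment-effect parameters, version 1.
#
# rr_per_10mmHg are synthetic stand-in gradients: the relative risk of a new
# event multiplies by this factor for every 10 mmHg of SBP above the
# reference category (the bin containing the 110-115 mmHg theoretical
# minimum-risk level). They encode the standard log-linear SBP-CVD dose
# response; replace with study-specific values where available.
version: 1
rr_per_10mmHg:
  ihd: 1.40
  hhd: 1.60
  ischemic_stroke: 1.50
  hemorrhagic_stroke: 1.60
# Relative reductions in case fatality attributable to pharmacological blood
# pressure treatment among prevalent cases (secondary prevention).
relative_cf_reduction:
  ihd_with_heart_failure: 0.20
  ihd_without_heart_failure: 0.26
  ischemic_stroke: 0.36
  hemorrhagic_stroke: 0.76
  hhd: 0.20
heart_failure_share_ihd: 0.30
# Mean SBP reduction (mmHg) per gram of reduced daily sodium intake.
sodium_sbp_slope:
  raised_bp: 1.12
  normal_bp: 0.58
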