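# Default cohort simulation parameters: group sizes, biomarker
# distributions and the linear links (response: DTI-ALPS) that set the
# correlation structure between biomarkers. Centiloid is the exogenous
# stage variable; ALPS is generated from it, and MMSE / VSRAD are
# generated from ALPS by inverting their links.
groups:
  n_cn: 27
  n_ad: 56
sex_m:            # males per group (remainder female)
  cn: 11
  ad: 28
age:
  cn: {mean: 69.3, sd: 9.6}
  ad: {mean: 69.9, sd: 10.6}
centiloid:
  cn: {mean: 0.4, sd: 6.7}
  ad: {mean: 78.5, sd: 33.4}
links:            # ALPS = intercept + slope * predictor, Pearson r over all subjects
  alps_b1000:
    centiloid: {slope: -0.0018, intercept: 1.436, r: 0.65}
    mmse:      {slope: 0.017,   intercept: 0.902, r: 0.55}
    vsrad:     {slope: -2.65,   intercept: 5.16,  r: 0.40}
  alps_b2000:
    centiloid: {slope: -0.0014, intercept: 1.386, r: 0.47}
    mmse:      {slope: 0.012,   intercept: 1.002, r: 0.37}
    vsrad:     {slope: -1.41,   intercept: 3.47,  r: 0.22}
centiloid_anchors:  # calibration inputs for the SUVR -> centiloid transform
  suvr_yc: 1.009
  suvr_ad100: 2.076
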