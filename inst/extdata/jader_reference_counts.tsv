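# Marginal counts of the full-scale JADER patient-based dataset
# (reports submitted April 2004 - November 2021), as published for the
# survey this pipeline implements. Desk-scale runs cannot reproduce these;
# they are shipped as plain-text inputs for the percentage arithmetic.
category	count
patients_total	638876
male	326427
female	312449
age_60s	143724
age_70s	164456
kampo_users	5566
dili_patients	51110
kampo_dili_patients	1701
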