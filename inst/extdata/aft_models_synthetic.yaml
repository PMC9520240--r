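# SYNTHETIC stipulated Weibull AFT coefficient sets.
# These are configuration defaults calibrated against the package's own
# synthetic cohort generator (so that roughly 10.5% of generated adults
# fall in the 10-20% 10-year risk band); they are NOT estimates from any
# registry dataset. Parameterization: S(t|x) = exp(-(t/lambda)^k) with
# lambda = exp(intercept + x.beta) on log-time and k = 1/scale.
parameterization: weibull_aft_logtime
note: synthetic defaults, calibrated to the packaged cohort generator
incidence_no_prs:
  intercept: 6.954
  scale: 0.7692307692307693
  coefficients:
    age: -0.020
    male: -0.150
    findrisc: -0.090
incidence_with_prs:
  intercept: 6.954
  scale: 0.7692307692307693
  coefficients:
    age: -0.020
    male: -0.150
    findrisc: -0.090
    prs: -0.250
complications:
  intercept: 3.60
  scale: 0.8333333333333334
  coefficients:
    age: -0.010
    male: -0.100
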