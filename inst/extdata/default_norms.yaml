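# Default normative model for 90-s verbal-fluency tests.
#
# Regression coefficients are the published normative equations relating
# correct words (CW) to years of education and daily computer use
# (Likert 1-8) in a 180-subject adult cohort:
#   semantic ("animals"): CW = 10.61 + 0.781*Education + 0.912*Computer-use
#   phonemic ("F"):       CW =  9.65 + 0.356*Education + 0.789*Computer-use
# Residual SDs are not published directly; they are derived from the
# cohort CW standard deviations (6.9 semantic, 6.5 phonemic) and the
# regression R^2 (17.0% and 8.5%) as SD * sqrt(1 - R^2).
#
# Control-distribution tail thresholds (semantic condition) are derived
# from the cohort means and SDs under a normal-tail approximation; refit
# with fit_norms() on a local control cohort for empirical thresholds.
semantic:
  intercept: 10.61
  coef_education: 0.781
  coef_computer_use: 0.912
  residual_sd: 6.287
phonemic:
  intercept: 9.65
  coef_education: 0.356
  coef_computer_use: 0.789
  residual_sd: 6.218
thresholds:
  mean_syllables:
    tail: lower
    p05: 1.462
    p10: 1.545
  mean_lwf:
    tail: upper
    p05: 3.748
    p10: 3.715
  typicality_pct:
    tail: upper
    p05: 33.95
    p10: 32.02
  pct_repeats:
    tail: upper
    p05: 6.73
    p10: 5.53
  tdp:
    tail: upper
    p05: 79.45
    p10: 75.82
soi_mean: 2.07
soi_sd: 0.7
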