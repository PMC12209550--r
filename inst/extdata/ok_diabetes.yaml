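# OK-Diabetes worked example: re-design of a feasibility study of supported
# self-management in adults with learning disabilities and type II diabetes.
# Endpoint: change in HbA1c (%) at 6 months, known SD 1.5; the target mean
# reduction of 0.5% is expressed on a positive, larger-is-better scale.
scenario:
  sigma: 1.5
  mu_star: 0.5
  prior:
    kind: univariate
    m: 0.0
    s: 0.6
  utility:
    d_bar: 0.005
    d_hat: 0.3
    n_star: 50
    rho: 2.0
constraints:
  n1_min: 30        # pilot must still address its feasibility objectives
  pilot_type: external
options:
  nodes: 151
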