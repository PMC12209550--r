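# pilotopt

Bayesian decision-theoretic design of two-stage trial programmes: an
external or internal pilot trial followed by a definitive trial, two-arm
parallel-group, normally distributed endpoint with known standard
deviation σ, one-sided superiority z-tests at each stage.

Pilot trials usually avoid testing effectiveness because a conventionally
sized test (α in 0.01–0.1) would be hopelessly underpowered at pilot
sample sizes. But "don't test" is itself a test with α = 1, β = 0, and
nothing forces pilot error rates into the conventional range. `pilotopt`
treats the choice of per-arm sample sizes and critical values
z = (n₁, c₁, n₂, c₂) as a decision problem: construct a utility over the
programme's terminal state from a handful of elicited quantities, average
it over a prior on the true effect, and maximise.

**Model.** Stage i observes the mean difference xᵢ | μ ~ N(μ, 2σ²/nᵢ) and
is positive when xᵢ > cᵢ; a positive pilot proceeds, a positive definitive
trial adopts the intervention. Value is linear in three attributes —
total per-arm sample size n, realised change in mean outcome d, and
control retention b:

v(n, d, b) = kₙn + k_d d + k_b b,  with
k_d = 1/(1 + d̂ − d̄/n*), kₙ = −k_d d̄/n*, k_b = 1 − k_d − kₙd̂,

where d̄ is the outcome change worth a sample-size increase from 0 to n*
and d̂ the change justifying a switch of treatments. Risk attitude enters
through the exponential (CARA) transform u = 1 − e^(−ρv) (ρ > 0
risk-averse; ρ recovered from the certainty equivalent of a 50/50 gamble).
Expected utility integrates the three terminal branches over a normal
prior μ ~ N(m, s²) by Gauss–Hermite quadrature; internal pilots pool the
pilot data into the final test (bivariate normal of pilot and pooled
means), and a bivariate prior with correlation τ allows the pilot and
definitive effects to differ. Utility gaps are reported in
participant-equivalent units (value gap divided by |kₙ|).

## Worked example

The bundled scenario re-designs OK-Diabetes, a feasibility study of
supported self-management for adults with learning disabilities and type
II diabetes: HbA1c-change endpoint with σ = 1.5, sceptical prior
N(0, 0.6²), target difference μ* = 0.5, elicited d̄ = 0.005, d̂ = 0.3,
n* = 50, risk attitude ρ = 2, and a pilot of at least 30 per arm for its
feasibility objectives.

```r
library(pilotopt)
sc  <- ok_diabetes_scenario()
opt <- optimise_programme(sc, design_constraints(n1_min = 30))
np  <- optimise_programme(sc, design_constraints(n1_min = 30,
                                                 no_pilot_test = TRUE))
format_programme_table(programme_table(list(unrestricted = opt,
                                            `no pilot test` = np)))
#>        problem pilot_type n1  n2 alpha1 beta1 alpha2 beta2 alpha_t beta_t
#>   unrestricted   external 41 146  0.389 0.110  0.041 0.133   0.016  0.228
#>  no pilot test   external 30 110  1.000 0.000  0.035 0.253   0.035  0.253
#>       eu
#>  0.42869
#>  0.42287

regret_in_participants(opt$expected_utility, np$expected_utility, sc$utility)
#> [1] 65.84717
```

The optimal programme tests the pilot at a one-sided α₁ ≈ 0.39 — far
above the conventional range — keeping pilot power at 0.89 with only 41
per arm, and compensates with a stricter definitive test (α₂ ≈ 0.041,
overall α_t ≈ 0.016, overall power 0.77). Refusing to test the pilot
costs 0.0058 in expected utility, equivalent to recruiting and following
up about 66 extra participants. `optimise_internal()` finds the
internal-pilot optimum (n₁ = 45, n₂ = 121, α₁ ≈ 0.42, slightly higher
expected utility, as pooling the pilot data should give), `tau_sweep()`
shows the pilot test weakening as the pilot effect decouples from the
definitive effect (α₁ → 1 by τ ≈ 0.6), and `regret_at()` /
`regret_surface()` quantify the cost of mis-specified prior or utility
parameters in participant units.

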