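---
title: "Decision-theoretic design of pilot and definitive trial programmes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-theoretic design of pilot and definitive trial programmes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pilotopt)
```

## The design problem

A two-arm parallel-group pilot trial is to be followed, if it succeeds, by a
two-arm definitive trial of the same intervention. Both compare intervention
to control on a normally distributed primary endpoint with known common
standard deviation $\sigma$, testing superiority one-sided. Stage
$i \in \{1, 2\}$ observes the mean difference $x_i$ with sampling
distribution $x_i \mid \mu \sim N(\mu,\, 2\sigma^2/n_i)$ and declares a
positive result when $x_i > c_i$. A positive pilot proceeds to the
definitive trial; a positive definitive trial adopts the intervention. The
design variable is $z = (n_1, c_1, n_2, c_2)$: per-arm sample sizes and
critical values. Equivalently, each stage can be summarised by its
operating characteristics $\alpha_i = \Pr[x_i > c_i \mid \mu = 0]$ and
$\beta_i = \Pr[x_i \le c_i \mid \mu = \mu^*]$ at a stated alternative
$\mu^*$; for an external pilot the stages are independent given $\mu$, so
the programme-level rates compose as $\alpha_t = \alpha_1\alpha_2$ and
$\beta_t = \beta_1 + (1-\beta_1)\beta_2$.

Convention has pilot trials avoid testing effectiveness at all — the
degenerate rule $\alpha_1 = 1, \beta_1 = 0$. The question this package
answers is whether, and by how much, that convention loses relative to an
optimally chosen pilot test. It does so by maximising expected utility
under a prior on $\mu$.

## Utility

Preferences are defined over three attributes of the programme's terminal
state: the total sample size $n$ (the sum of the per-arm stage sizes
actually recruited), the realised change in mean outcome $d$ ($\mu$ if the
intervention is adopted, 0 otherwise), and an indicator $b$ of retaining
control. A linear value function

$$v(n, d, b) = k_n n + k_d d + k_b b$$

is pinned down by two elicited quantities: $\bar d$, the outcome change
that would justify growing the total sample size from 0 to a reference
$n^*$; and $\hat d$, the outcome change that would justify switching from
control to the new intervention. These give

$$k_d = \frac{1}{1 + \hat d - \bar d / n^*}, \qquad
  k_n = -k_d \bar d / n^*, \qquad k_b = 1 - k_d - k_n \hat d,$$

implemented in `derive_weights()`. The attitude to risk enters through a
constant-absolute-risk-aversion transform with parameter $\rho$:
$u = 1 - e^{-\rho v}$ for $\rho > 0$, $u = v$ at $\rho = 0$, and
$u = -1 + e^{-\rho v}$ for $\rho < 0$. `rho_from_gamble()` recovers $\rho$
from the certainty equivalent of a 50/50 gamble on the $d$ attribute alone
(with $n = 0$, $b = 0$, so the gamble's value equals $d$ before
weighting) — this is the convention under which a certainty equivalent of
0.19 on a $(0, 0.5)$ gamble corresponds to $\rho = 2$. Note the raw
utilities scale with $\rho$ near zero; utility is unique only up to
positive affine transformation, and the normalised form $u/|\rho|$ tends to
the linear branch, so preferences are continuous in $\rho$ even though the
reported utility numbers are not.

Differences on the utility scale are hard to interpret, so the package
routinely converts them to *participant-equivalent* units: map utilities
back to values with $-\tfrac{1}{\rho}\log(1-u)$ and divide the value
difference by $|k_n|$ (`regret_in_participants()`). A gap of 66
participants means the better design is worth as much as being spared the
recruitment and follow-up of 66 participants.

## Expected utility

Conditional on $\mu$, the programme ends in one of three branches — adopt
($G_1 = G_2 = 1$, value $k_d\mu + k_n(n_1+n_2)$), stop after a negative
definitive trial ($k_n(n_1+n_2) + k_b$), or stop after a negative pilot
($k_n n_1 + k_b$) — with probabilities given by the stage sampling
distributions (`branch_probabilities()`, `conditional_eu()`). The prior
$\mu \sim N(m, s^2)$ is a subjective design prior, used only to weight
operating characteristics, never in the trial analysis. The prior integral
is evaluated by Gauss–Hermite quadrature with the change of variable
$\mu = m + \sqrt{2} s t$.

**Node count.** The integrand multiplies the smooth conditional expected
utility (which varies on the scale of the stage standard errors, roughly
$0.1$–$0.3$ here) against a prior with $s = 0.6$, and quadrature converges
more slowly than one might guess: in the bundled worked example a 35-node
rule still carries an absolute error near $2\times 10^{-4}$ — enough to
displace the optimiser's solution by several participants — while 151
nodes is stable to $\sim 10^{-9}$ under node doubling and against a
composite-Simpson brute-force integral. The default is therefore
`nodes = 151`; `eu_convergence()` repeats the doubling check for any new
scenario, which is advisable when the prior is much tighter than the stage
standard errors.

## Internal pilots and heterogeneous effects

For an *internal* pilot the definitive analysis pools the pilot data,
testing $x_t = (n_1 x_1 + n_2 x_2)/(n_1 + n_2)$ against $c_2$. Given
$\mu$, $(x_1, x_t)$ is bivariate normal with variances $2\sigma^2/n_1$ and
$2\sigma^2/(n_1+n_2)$ and covariance equal to the latter (correlation
$\sqrt{n_1/(n_1+n_2)}$), so branch probabilities are upper-orthant
probabilities of that joint law. These are computed by a vectorised
Gauss–Legendre evaluation of the conditional decomposition
$\int_h^\infty \phi(x)\,\bar\Phi\!\big((k - rx)/\sqrt{1-r^2}\big)\,dx$,
splitting off the region where the inner factor is numerically 0 or 1
(where the integral is a closed-form normal probability). The routine
agrees with `mvtnorm::pmvnorm` to better than $10^{-10}$ across
$|r| \le 0.9999$ (it is tested against it), and being vectorised over
quadrature nodes it keeps a full internal-pilot optimisation at around ten
seconds. The stage-2 level $\alpha_2$ of an internal design is defined on
the pooled statistic's null distribution; since the stages share data, the
programme-level $\alpha_t = \Pr[x_1 > c_1, x_t > c_2 \mid \mu = 0]$ no
longer factorises and is reported from the joint law.

The *heterogeneous-effects* extension drops the assumption that the pilot
and definitive trials share one true effect: $(\mu_p, \mu)$ follows a
bivariate normal prior with correlation $\tau$. Marginalising $\mu_p$, the
pilot estimate given the definitive effect is
$x_1 \mid \mu \sim N\!\big(m_p + \tau \tfrac{s_p}{s}(\mu - m),\,
(1-\tau^2)s_p^2 + 2\sigma^2/n_1\big)$: imperfect correlation both biases
the pilot towards its own marginal mean and inflates its variance, eroding
its value as a screen. The adopt-branch payoff keeps $d = \mu$ — the
definitive-trial effect is the quantity whose change matters after
adoption. With $\tau = 1$ and matched marginals the homogeneous model is
recovered exactly (this is tested to $10^{-10}$).

## Optimisation

`optimise_programme()` maximises expected utility over $z$. Sample sizes
are relaxed to continuous values on a log scale and stage alphas moved to
a logit scale, which frees the box-constrained quasi-Newton search
(`optim(method = "L-BFGS-B")`, numerical gradients) from all edges except
the stated bounds and improves conditioning. Thirty-two deterministic
start points (a $4 \times 4$ grid on the stage alphas crossed with two
sample-size heuristics: near the lower bounds, and near a
conventional-power design) guard against local optima; the surface is
smooth but can be flat along a ridge trading $n_1$ against $\alpha_1$.
The integer neighbourhood ($\pm 2$ per stage) of the continuous solution
is then searched exhaustively with the critical values re-optimised for
each candidate — plain rounding is not reliable because expected utility
is asymmetric around the continuous optimum. Ties within $10^{-10}$
prefer smaller $n_1 + n_2$, then smaller $n_1$.

The log-scale relaxation cannot reach $n = 0$, so degenerate programmes
are evaluated as explicit boundary candidates: pilot-only ($n_2 = 0$,
adopt on a positive pilot), definitive-only ($n_1 = 0$, where permitted),
and no-trial. A stage with $n = 0$ follows the convention
$\alpha = 1, \beta = 0$ (always proceed). The `no_pilot_test` constraint
fixes $n_1$ at its lower bound with $c_1 = -\infty$ and optimises the
definitive stage alone. `rho_sweep()` and `tau_sweep()` re-optimise along
parameter grids, warm-starting each solve from its neighbour (plus the
full start grid, so a warm start can help but never trap the search).

## Sensitivity analysis

`regret_at()` asks what keeping a fixed proposed design costs if the prior
or utility parameters are in truth different: the programme is re-optimised
under the perturbed scenario and the expected-utility gap to the proposed
design converted to participants. The conversion uses the *perturbed*
scenario's $\rho$ and $k_n$, since both expected utilities live in that
scenario; regret is zero at the elicitation point by construction.
`regret_surface()` maps this over a grid of two parameters (prior mean and
SD, or risk attitude and sampling cost), warm-starting along the inner
loop; spot cells re-checked with cold starts agree to within a
participant. One caution from our own convergence study: regret values of
a few tens of participants sit near the resolution of the whole pipeline,
moving by $\pm 5$ or more participants when the quadrature is
under-resolved, so surfaces computed with fewer nodes than the default
should be read qualitatively.

## The simulator as an oracle

`simulate_programme()` executes programmes forward: draw $\mu$ (and
$\mu_p$) from the prior — or hold $\mu$ fixed to estimate error rates —
draw the stage statistics, apply the decision rules, average realised
utilities. It shares only the terminal value definitions with the analytic
path, so agreement (within three standard errors, across external,
internal and heterogeneous variants) is a genuine end-to-end check, and
the test suite uses it as such. Runs are reproducible given a seed.

## The worked example

The bundled configuration (`ok_diabetes_scenario()`) re-designs a
feasibility study of supported self-management for adults with learning
disabilities and type II diabetes. The endpoint is change in HbA1c (%) at
six months with $\sigma = 1.5$; the target difference $\mu^* = 0.5$ is a
mean *reduction* of 0.5%, mapped to a positive larger-is-better scale
throughout. The sceptical prior $N(0, 0.6^2)$ puts probability about 0.20
on $\mu \ge 0.5$. Elicited inputs $\bar d = 0.005$, $\hat d = 0.3$,
$n^* = 50$ give weights $(k_d, k_n, k_b) = (0.769, -7.69\times 10^{-5},
0.231)$, and a certainty equivalent of 0.19 on the $(0, 0.5)$ gamble gives
$\rho = 2$. The pilot must keep $n_1 \ge 30$ for its feasibility
objectives.

```{r worked-example}
sc <- ok_diabetes_scenario()
opt <- optimise_programme(sc, design_constraints(n1_min = 30))
np <- optimise_programme(sc, design_constraints(n1_min = 30,
                                                no_pilot_test = TRUE))
format_programme_table(programme_table(list(unrestricted = opt,
                                            `no pilot test` = np)))
regret_in_participants(opt$expected_utility, np$expected_utility,
                       sc$utility)
```

The unrestricted optimum tests the pilot at a strikingly large one-sided
$\alpha_1 \approx 0.39$ — far outside the conventional 0.01–0.1 range —
and the refusal to test at all costs the equivalent of about 66
participants.

## Scope and limitations

The model assumes a known, common outcome SD and z-tests; unknown-variance
and unequal-variance analyses, more than one interim look, efficacy
stopping at the pilot, posterior updating between stages, set-up costs and
non-normal priors are out of scope. The synthetic scenarios the tests run
are exactly the model's own data-generating process (normal endpoints,
normal priors), so passing tests demonstrate internal correctness and
faithful reproduction of the worked example — not robustness of the design
recommendations to model misspecification in real trials. Expected-utility
surfaces here are well behaved, but the optimiser is local-with-multistart,
not certified global; for new problem classes it is worth cross-checking a
few solutions against an exhaustive search over $(n_1, n_2)$ with profiled
critical values, as the test suite does for the worked example. Reported
test sizes: Monte Carlo cross-checks in the tests use $2$–$4 \times 10^5$
replicates, which resolves expected utilities to roughly $\pm 10^{-3}$ at
three standard errors.
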