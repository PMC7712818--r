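---
title: "Dissecting moral dilemma judgments with the CNI processing tree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting moral dilemma judgments with the CNI processing tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moralmpt)
library(dplyr)
```

## The problem

In a moral-dilemma battery each scenario pits a moral norm against the
consequences of acting. The batteries handled here cross two factors over six
base scenarios: the norm either *proscribes* the action (it forbids, e.g.,
killing one person) or *prescribes* it (it demands, e.g., rescuing), and the
benefits of acting are either *greater* or *smaller* than its costs. That
yields four dilemma types and 24 items; the subject gives a binary
action/inaction judgment on each.

Traditional scoring reads action on the proscriptive, benefits-greater items
as "utilitarian" and inaction as "deontological". That confounds three
different things: caring about consequences, caring about norms, and simply
preferring not to act. The CNI multinomial processing tree separates them.

## The model

For each judgment, with probability $C$ the subject follows the
*consequences* (acts iff benefits exceed costs); otherwise, with probability
$N$, the subject follows the *norm* (inaction under a proscriptive norm,
action under a prescriptive one); otherwise a general response bias applies:
inaction with probability $I$, action with probability $1 - I$. Writing
$a = C$, $b = (1-C)N$, $c = (1-C)(1-N)(1-I)$, the action probabilities for
the four types are

| type (norm / benefits)    | $p(\text{action})$ |
|---------------------------|--------------------|
| proscriptive / greater    | $a + c$            |
| proscriptive / smaller    | $c$                |
| prescriptive / greater    | $a + b + c$        |
| prescriptive / smaller    | $b + c$            |

Two algebraic identities follow and are verified in the test suite:
$p_1 + p_4 = p_2 + p_3$ for every parameter value, and the link to the older
process-dissociation (PD) decomposition: on the proscriptive types,
$U = C$ and $D = N + (1-N)I$ exactly. The PD formulas themselves are

$$U = p(\text{unacceptable}\mid\text{congruent}) -
      p(\text{unacceptable}\mid\text{incongruent}), \qquad
  D = \frac{p(\text{unacceptable}\mid\text{incongruent})}{1 - U},$$

where "unacceptable" is the inaction response on a proscriptive dilemma,
*congruent* means benefits smaller than costs and *incongruent* benefits
greater. $D$ is undefined at $U = 1$; we report it as `NA` and count the
exclusions rather than impute, since any imputation would be arbitrary.

## Estimation

Responses are aggregated over subjects into per-type action counts — the
sufficient statistic of a product-binomial likelihood. `cni_fit()` minimizes
the likelihood-ratio statistic

$$G^2 = 2 \sum_{\text{cells}} \mathrm{obs} \cdot
        \ln(\mathrm{obs}/\mathrm{exp}),$$

equivalently maximizes the likelihood, over the unit cube with bounded
quasi-Newton iterations (`optim` L-BFGS-B) from a fixed 10-point lattice of
starting values; ties between starts resolve to the lowest $G^2$. The
single-group model leaves $4 - 3 = 1$ degree of freedom, so $G^2$ doubles as
a goodness-of-fit test. Standard errors come from the inverse observed
information (numerical Hessian of the negative log-likelihood at the
optimum) and Wald intervals are truncated to $[0, 1]$. Counts may be
real-valued: group means printed to two decimals multiply back into
fractional counts, and $G^2$ is applied to them verbatim, which is exactly
what re-analysis of published aggregates requires.

Numerical notes. Inside the optimizer the log-likelihood clamps
probabilities to $[10^{-12}, 1-10^{-12}]$ so boundary parameter values stay
finite; the user-facing `cni_g_squared()` keeps the exact convention
($0\ln 0 = 0$; expected probability 0 against a positive observed count is
$+\infty$ with a warning). Convergence tolerance is `factr = 1e4`
(about $10^{-12}$ relative on $G^2$). A type with no observations
contributes nothing.

Aggregation ignores subject clustering, as in the standard aggregate MPT
analysis; under strong between-subject heterogeneity the standard errors are
anti-conservative. This is a documented limitation, and the simulator's
heterogeneity switch exists precisely to probe it.

## Group comparison

`cni_fit_joint()` maximizes the summed log-likelihood over several groups
under optional constraints: a parameter equal across groups, or fixed at a
value (0 and 0.5 are the conventional reference points). The unconstrained
two-group baseline has $8 - 6 = 2$ degrees of freedom.
`cni_test_equality()` and `cni_test_point()` form
$\Delta G^2 = G^2_{\text{constrained}} - G^2_{\text{unconstrained}}$,
referred to a chi-square distribution with as many degrees of freedom as
independent constraints — one for a single-parameter equality test across
two groups, and one for a point hypothesis. Constrained fits reuse the
unconstrained solution as an additional warm start, which keeps the nesting
inequality ($\Delta G^2 \ge 0$) reliable in practice. Point hypotheses at a
parameter boundary keep the chi-square reference but carry a warning, since
the asymptotics there are only approximate; no boundary-mixture correction
is applied.

## The bundled aggregates

`psychopathy_fixture()` ships the per-type mean action scores (0–6), group
sizes, and LSRP summary statistics of a published extreme-groups comparison
(top vs bottom 20% of LSRP totals, $n = 174$ high vs $188$ low). Everything
below is recomputed from those means at run time:

```{r fixture}
fx <- psychopathy_fixture()
fit_high <- cni_fit(filter(fx$counts, group == "high"))
fit_low  <- cni_fit(filter(fx$counts, group == "low"))
round(rbind(high = fit_high$estimates, low = fit_low$estimates), 2)
tidy(cni_test_equality(fx$counts, "N", se = FALSE))
pd_from_counts(fx$counts)
```

The groups differ markedly in norm sensitivity ($N$), not in consequence
sensitivity ($C$) or action bias ($I$); both $I$ estimates fall just below
0.5 (a slight preference for action). Because the printed means are rounded
to two decimals, $\Delta G^2$ statistics recomputed from them match the
originally reported ones to within a few percent, not exactly; the
parameter estimates themselves are stable to the displayed precision. Note
one subtlety: group-level $D$ computed from aggregate proportions is a
ratio of means, while a per-subject analysis averages ratios — the two
differ (Jensen's inequality), so aggregate $D$ need not equal a published
per-subject mean $D$.

## Scale scoring and grouping

`score_lsrp()` scores the 26-item LSRP (six-point Likert items; reverse-keyed
items scored $7 - v$) into total, primary, and secondary scores. The keying
is a configuration input: the shipped default (items 1–16 primary, 17–26
secondary, no reverse keys) is positional and should be replaced by the
keying of the administration actually used, via `lsrp_keying()` or a
JSON/YAML file. `assign_groups()` ranks totals and labels the top and bottom
`round(quantile * n)` subjects (ties broken by ascending subject id, so the
rule is deterministic and group sizes never inflate at a tied boundary).
`cronbach_alpha()`, `two_group_t()` (Student pooled by default, Welch behind
a flag — pooled matches the equal-variance style of the reports this
package reproduces), `cohens_d_from_stats()` and `pearson_r()` cover the
accompanying descriptive statistics.

## The synthetic-cohort generator

`simulate_cohort()` draws, per subject, 24 binary responses from the CNI
tree at the group's parameters and an LSRP total from the group normal
(rounded, clipped to 26–156), then item responses that sum exactly to the
total by distributing the surplus uniformly over item slots. Defaults follow
the study conditions the fixture documents: group sizes 174/188, LSRP
normals $N(84.21, 6.39^2)$ and $N(47.44, 6.28^2)$, and CNI parameters at the
published group estimates are used throughout the tests. Seeding is
hierarchical — the cohort seed yields one sub-seed per subject — so a
subject's data does not depend on how many subjects precede it.

What the generator emulates: the tree's response process, extreme-group
separation on the trait scale, and (optionally) between-subject parameter
heterogeneity via $\mathrm{Beta}(\mu\kappa, (1-\mu)\kappa)$ perturbations
whose mean equals the group parameter. What it does not emulate: item-level
covariance of the questionnaire (only totals are distributionally faithful,
so internal-consistency statistics on synthetic items are floor cases, not
realistic ones), scenario-specific difficulty, order effects, and response
times. Passing parameter-recovery tests on this generator therefore
demonstrates correctness of the estimation machinery under the model's own
assumptions, not robustness to real-data violations of them — except for
the heterogeneity checks, which probe exactly one such violation.

## Problem sizes used in the checks

The test suite exercises: noiseless recovery at 600 trials per type
(agreement to $10^{-6}$); equivalence with an exhaustive $10^{-3}$-step grid
search on small counts (two-stage exhaustive grid, same resolution);
parametric-bootstrap validation of Wald intervals (2,000 draws at 200 trials
per type); type-I error calibration of the equality test (2,000 null
replicates at 1,000 trials per type, $0.05 \pm 0.015$); power of the
$I = 0.5$ point test at the full-cohort scale (200 replicates, 869 subjects);
and confidence-interval coverage over 100 cohorts at the fixture's group
sizes. These sizes were chosen so each property is measured with comfortable
Monte-Carlo margin while the whole suite stays quick to run.

## Known limitations

- Aggregate-only estimation: no hierarchical (beta-MPT / latent-trait)
  extensions; subject clustering is ignored in the likelihood.
- Boundary hypotheses use the plain chi-square reference.
- The default LSRP keying is a positional placeholder, not an endorsement of
  any particular published keying.
- Group-level $D$ from aggregates is a ratio of means (see above) and is not
  comparable to per-subject mean $D$ without care.
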