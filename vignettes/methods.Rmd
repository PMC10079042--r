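---
title: "Methods: models, priors and design choices in breechscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, priors and design choices in breechscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breechscan)
```

`breechscan` evaluates a maternity screening-policy change — universal
late-pregnancy ultrasound for fetal presentation — by comparing two
epochs of routinely collected birth records. This vignette is the
package's own account of the statistical machinery: what is modelled,
which knobs matter, what the synthetic cohorts do and do not emulate, and
where a design was genuinely open and a choice had to be made.

## Cohort definitions

A record is one birth. The exclusions applied by `apply_exclusions()` are
the conventional ones for this design: multiple pregnancies, preterm
births, and congenital anomalies, the latter because anomalies both
confound neonatal outcomes and alter delivery planning. *Term* is fixed
at a gestational age of at least 259 days (37+0 weeks); 258 days is
preterm, 259 is term, and the boundary is tested.

An *undiagnosed breech* (`classify_undiagnosed_breech()`) is a term
breech birth with no antenatal diagnosis whose breech presentation was
first found after the onset of labour, after rupture of membranes, or
immediately before induction. Any antenatal detection, at whatever visit,
counts as diagnosed — no look-back window is imposed, since a scan that
found breech at any point gave the care team the information the policy
is meant to provide.

Epoch assignment (`epoch_spec()`) is a half-open interval on the birth
date: strictly before the policy cut date is "before", on or after is
"after". Sites phase policies in over months; the cut date is the point
of *complete* adoption and is deliberately a configuration input, not an
inference target.

Records with a planned cesarean *for breech* can be excluded from
non-neonatal outcome denominators (`apply_planned_cs_rule()`); neonatal
outcomes (5-minute Apgar < 7, neonatal-unit admission, hypoxic ischemic
encephalopathy, extended perinatal mortality) always keep them, because a
baby delivered by planned cesarean still contributes neonatal risk
information. Published audit tables in this area typically keep elective
cesareans for diagnosed breech inside the breech denominators, so the
`planned_cesarean_for_breech` flag should be read as "excluded by the
site's analysis protocol", not as a synonym for elective cesarean mode;
the synthetic generator plants no such flags unless asked.

Missing fields (for example an unrecorded Apgar score) drop a record from
that outcome's denominator only, with the dropped count attached to the
summary — missingness in one variable should not shrink every analysis.

## The Bayesian log-binomial model

For events $a/n_1$ before and $c/n_2$ after:

$$a \sim \mathrm{Bin}(n_1, e^{\alpha}), \qquad
  c \sim \mathrm{Bin}(n_2, e^{\alpha + \beta}),$$

so $e^{\beta}$ is the risk ratio. The log link is what makes the
coefficient a *risk* ratio rather than an odds ratio — the natural scale
for communicating a screening effect — at the cost of a bounded
parameter space: both fitted risks must stay at or below one. The
support constraint $\alpha \le 0,\ \alpha + \beta \le 0$ is enforced
exactly by rejecting proposals outside it.

Priors:

* $\beta \sim N(\mu, \sigma)$. `elicit_normal_prior()` converts a
  published risk ratio and 95% CI into $(\mu, \sigma)$ by
  $\mu = \log \mathrm{RR}$ and $\sigma = (\log \mathrm{hi} - \log
  \mathrm{lo}) / (2 \times 1.959964)$. The constant 1.959964 (rather
  than 1.96) is fixed so the elicitation and its round-trip inverse agree
  to full precision; the numerical difference is negligible.
* The sensitivity default (`weakly_informative_prior()`) is
  $N(0, 10)$ — wide enough on the log scale that the likelihood
  dominates for any realistic cohort. A truly improper flat prior
  (`rr_prior(0, Inf, flavour = "flat")`) exists behind a flag, and on
  these data is indistinguishable from the weak default.
* $\alpha \sim t_3(\mathrm{location}, 2.5)$. The location defaults to the
  log pooled risk of the data being fitted — a convenient, data-scaled
  centring; with scale 2.5 on the log scale the prior is far too diffuse
  to move the intercept materially, and both location and scale are
  configurable for anyone who wants a genuinely informative intercept.

When one epoch has zero events the log-scale RR is undefined;
`zero_event_correction()` adds a single event to the zero cell, leaving
the denominator unchanged. When *both* epochs have zero events the
orchestrator reports the outcome as not estimable rather than
manufacturing information from two corrections.

### Sampler

`fit_logbinomial()` runs an adaptive random-walk Metropolis sampler on
$(\alpha, \beta)$ jointly: Gaussian proposals, scales adapted every 50
iterations *during burn-in only* toward a 35% acceptance rate, then
frozen so the retained chain satisfies detailed balance. Defaults are two
chains of 1,500 retained iterations after 500 burn-in — small by modern
standards but sufficient here because the posterior is two-dimensional
and unimodal; the chains are checked with Gelman–Rubin R-hat (warning
above 1.05) and the acceptance rate (warning outside 0.1–0.6). Chain $i$
is seeded with `seed + i - 1` on a private RNG stream, so results are
bit-reproducible and the caller's random-number state is never touched.

Initial values are the empirical log risks with a half-event continuity
offset; when the $\beta$ prior is tight the start point is
precision-weighted toward $\mu$ so a narrow prior does not strand the
chain a long random walk away from its mass.

Summaries are the posterior *median* of $e^{\beta}$ (robust to the
right-skew of a ratio; the mean would be systematically larger) and the
equal-tailed 2.5/97.5 percentile interval. The probability of reduction
is computed by fitting a normal distribution by moments to the pooled
$\beta$ draws and evaluating its CDF at zero — a smoothed tail estimate
that is stable when the empirical tail contains only a handful of draws;
the test suite checks it stays within two percentage points of the
empirical fraction of draws below zero.

### The grid oracle

`grid_posterior_oracle()` is an independent check on the sampler, not a
convenience: it evaluates the unnormalised posterior on a fine 2-D grid,
normalises by quadrature, and reads the marginal median, interval and
$P(\beta < 0)$ straight off the marginal CDF with linear interpolation
inside grid cells. Grid bounds come from a precision-weighted normal
approximation (likelihood moments combined with the prior), extended to
±12 standard deviations per parameter, so the grid stays fine whether
the prior is tight or effectively flat; a grid whose mass underflows
raises an error rather than returning nonsense. The test suite compares
sampler and oracle across randomised small tables (median within three
Monte-Carlo standard errors, interval endpoints within 5%), using long
chains — 50,000 retained iterations per chain — so that Monte-Carlo
noise cannot mask a genuine disagreement.

## Number needed to scan

With risks $p_1 > p_2$, the number needed to scan is
$\lceil 1/(p_1 - p_2) \rceil$: the women scanned under the new policy per
undiagnosed breech prevented. The interval inverts the Wald interval for
the risk difference ($\mathrm{RD} \pm 1.959964\,\mathrm{SE}$,
$\mathrm{SE} = \sqrt{p_1(1-p_1)/n_1 + p_2(1-p_2)/n_2}$). Endpoints are
rounded *outward* (floor the lower, ceil the upper): an NNS interval is a
communication device and outward rounding never overstates precision;
nearest-integer rounding of the same bounds differs by at most one and is
noted here for anyone comparing conventions. A risk difference at or
below zero, or an interval crossing zero, is reported as "NNS undefined"
or an unbounded upper limit respectively — never silently truncated.

## Interrupted time series

`aggregate_monthly()` bins term breech records into calendar months with
no silent gaps (empty months appear with zero exposure), and
`fit_its()` regresses monthly counts on a natural cubic spline in month
index plus an epoch indicator, testing the indicator with an F test
between the models with and without it. The spline df default of 4 gives
the secular trend a gentle curvature budget over a five-to-six-year
series without letting it impersonate a step at the cut date; a
saturated or collinear design errors with advice to lower the df.
Gaussian least squares on counts is the default because monthly counts
at whole-maternity-unit exposure are large enough for the F test to be
well calibrated (the suite verifies type-I error against binomial 99%
bounds over 500 null replicates); a Poisson log-link variant with a
log-exposure offset is available for sparser series. The power check
plants the policy-scale step (event rate 0.142 falling to 0.028 against
monthly exposures of ~365) over a 46 + 20 month design. At the much
sparser scale of *undiagnosed counts among breech births only* (a mean
of one to two events per month), no monthly-count level-shift test has
meaningful power at stringent significance levels — the pooled 2×2
Bayesian comparison is the primary inference and the ITS is a
trend-shaped visual and sanity check, which is how it should be read in
the worked example.

## The synthetic cohort generator

`generate_cohort()` emulates exactly the structure the analysis assumes:
births uniform over each epoch's months, breech status Bernoulli (3.4%),
an undiagnosed fraction among breech of 14.2% before and 2.8% after the
policy, exclusion-criterion flags at realistic rates (1.5% multiple
pregnancies, 7% preterm, 2% anomalies), and rare adverse outcomes whose
risk depends on whether a breech was diagnosed (e.g. Apgar < 7: 0.8%
diagnosed vs 8% undiagnosed, 0.4% among non-breech so whole-cohort
tables are populated). Those conditional risks are simulation knobs
chosen to be epidemiologically plausible, not estimates. The generator
returns a `truth` tally computed by direct counting over the simulated
vectors — deliberately independent of the pipeline's aggregation code —
and the suite requires exact agreement between `summarise_outcome()` and
the tally across configurations, including ones that plant
protocol-excluded planned cesareans.

What the generator does *not* emulate, and what passing tests therefore
do not establish about real data: demographics (age, BMI, parity,
ethnicity, deprivation) are simple parametric families that never drive
outcome risk, matching the unadjusted two-group models fitted here but
not the confounding structure of real cohorts; there is no external
cephalic version pathway, no seasonality, no drift within epochs, and no
informative missingness. A single seeded RNG stream drives each cohort.

## Problem sizes and reproducibility

The test suite exercises the sampler-versus-oracle comparison on 20
randomised tables; parameter recovery at a planted risk ratio of 0.2,
0.5 and 1.0 with 100 replicates of 500-per-epoch cohorts (coverage of
the 95% interval required to sit in [0.90, 0.99]); generator calibration
over 200 replicates at 5,000 births per epoch; and ITS calibration over
500 null series. These sizes keep the full suite in the low minutes on a
single core while leaving Monte-Carlo error comfortably below every
tolerance being asserted. Every stochastic component takes an explicit
integer seed, and `run_full_analysis()` reruns byte-identically under a
fixed seed.

## Known limitations

* The two-group model is unadjusted; no covariate or hierarchical
  structure is offered, by design.
* The ITS module fits a fixed, known cut date — it does not search for a
  change point, and offers no autocorrelation-robust variance.
* The normal-density tail probability is a smoothing convention; for
  grotesquely skewed posteriors the empirical tail fraction (also
  returned via the draws) is the safer quantity.
* One published curiosity worth flagging for anyone cross-reading audit
  tables of this kind: a denominator printed as "60.7% [351/278]" in one
  source table is arithmetically 351/578 — the package never ingests
  printed percentages, only counts, precisely to be immune to such typos.
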