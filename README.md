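# breechscan

Breech presentation affects 3–4% of pregnancies at term. When it is first
discovered after labour has started — an *undiagnosed* breech — the options
of external cephalic version or a planned cesarean are gone, and the risk
of adverse neonatal outcomes rises. Several UK maternity units have moved
to universal late-pregnancy screening for fetal presentation, either a
routine 36-week departmental ultrasound or midwife-performed point-of-care
ultrasound (POCUS), and the natural evaluation design is a before/after
comparison of routinely collected birth records.

`breechscan` packages that evaluation as a tested, reusable pipeline for
epidemiologists and perinatal audit teams:

* **Cohort handling** — validated record-level CSV input, the standard
  exclusions (multiple pregnancy, birth before 37+0 weeks = 259 days,
  congenital anomaly), a planned-cesarean-for-breech rule that spares
  neonatal outcomes, and aggregation into two-epoch 2×2 summaries.
* **Descriptive comparisons** — Welch *t*, Wilcoxon rank-sum, and Pearson
  chi-squared (no continuity correction) epoch tables.
* **Bayesian risk ratios** — the analytical core. A log-binomial two-group
  model fitted by an adaptive random-walk Metropolis sampler written in
  this package, with priors elicited from published estimates and a
  deterministic grid-integration oracle to validate the sampler.
* **Number needed to scan** — inverted risk difference with a Wald
  interval.
* **Interrupted time series** — monthly counts on a natural-spline secular
  trend plus an epoch level shift, tested by an ANCOVA-style F test.
* **Synthetic cohorts** — a seeded generator with known ground truth, so
  every stage is testable without access to hospital records.

## The model

For event counts $a/n_1$ (before) and $c/n_2$ (after):

$$a \sim \mathrm{Bin}(n_1, p_1), \quad c \sim \mathrm{Bin}(n_2, p_2),
\qquad \log p_1 = \alpha, \quad \log p_2 = \alpha + \beta,$$

so $e^{\beta}$ is the after/before risk ratio (RR). Priors are
$\beta \sim N(\mu, \sigma)$ — elicited from a published RR and 95% CI via
$\mu = \log \mathrm{RR}$, $\sigma = (\log \mathrm{CI_{hi}} -
\log \mathrm{CI_{lo}})/(2 \times 1.959964)$, or the weakly informative
default $N(0, 10)$ — and a Student-t(3) prior on $\alpha$ centred at the
log pooled risk. The log link requires $p_g \le 1$, enforced by
constraining the support to $\alpha \le 0$, $\alpha + \beta \le 0$.
Reported are the posterior median RR, the equal-tailed 95% credible
interval, and the posterior probability of a reduction, computed from a
normal density fitted by moments to the log-RR draws. A zero event cell is
handled by adding a single event to that group. Sampling uses two chains
of 1,500 retained iterations after 500 of burn-in by default, with
Gelman–Rubin R-hat and acceptance-rate diagnostics.

## Worked example

```r
library(breechscan)

# a synthetic two-epoch cohort: 16,000 births over 46 months before the
# policy change, 7,000 over 20 months after, breech rate 3.4%, undiagnosed
# fraction falling from 14.2% to 2.8% of breech births
sim <- generate_cohort(sim_config(n_before = 16000, n_after = 7000,
                                  months_before = 46, months_after = 20,
                                  cut_date = "2020-01-01", seed = 42))

report <- run_full_analysis(analysis_config(
  sim$records, cut_date = "2020-01-01",
  priors = list(undiagnosed_breech = elicit_normal_prior(0.27, 0.19, 0.38)),
  mcmc = mcmc_config(seed = 42)))

print(report$summaries$undiagnosed_breech)
#> undiagnosed_breech: before 83/525 (15.8%) vs after 7/210 (3.3%)
print(report$fits$undiagnosed_breech$flat)
#> RR 0.19 (95% CrI 0.09, 0.43); P(reduction) 100.0%; R-hat 1.001; accept 0.34
print(report$fits$undiagnosed_breech$informative)
#> RR 0.26 (95% CrI 0.19, 0.35); P(reduction) 100.0%; R-hat 1.003; accept 0.34
cat("NNS:", report$nns$nns, " CI:", report$nns$ci, "\n")
#> NNS: 215  CI: 162 315
print(report$its)
#> ITS (gaussian, spline df = 4): epoch effect -1.062, F = 1.86, p = 0.1773
```

Reading the output: 15.8% of breech presentations reached labour
undiagnosed before the policy against 3.3% after; under a flat prior the
risk ratio is 0.19 (95% CrI 0.09–0.43), and the informative prior pulls
the estimate toward the external study's 0.27 while narrowing the
interval. About 215 women would need to be scanned to prevent one
undiagnosed breech. The interrupted time series works on *monthly*
undiagnosed counts (a mean of roughly two per month here), where a level
shift is much harder to distinguish from trend noise than in the pooled
2×2 comparison — hence the unremarkable F test on a cohort this size.

`run_full_analysis()` also writes `outcome_table.tsv`,
`descriptives.tsv`, `report.json` and `run.log` when given an `out_dir`.

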