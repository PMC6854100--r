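# tweedpanel

Bayesian Tweedie panel models of population change, with reversible-jump
covariate selection — for site-by-year abundance panels that are
non-negative and continuous *with an exact point mass at zero*, such as
winter garden-bird feeding counts averaged over weekly maxima.

## The problem and who this is for

Volunteer surveys of garden feeding stations record, per site and winter,
the mean of weekly maximum counts of each species.  These values are
zero-inflated (a species can be absent all winter), heavily right-skewed
(some gardens hold flocks), and the panel is unbalanced (sites join and
leave).  The scientific question is usually about *change*: does a
recovering predator (the Sparrowhawk) depress prey counts once winter
severity, location, habitat and a pseudo-predator control are accounted
for?  This package is for quantitative ecologists and biostatisticians
who want that full analysis chain as tested, reusable components.

## The model

Observations follow a Tweedie compound Poisson–gamma distribution,

    y_it ~ Tw(mu_it, phi, p),   Var(y) = phi * mu^p,   1 < p < 2,

which is a Poisson number of gamma summands: continuous on (0, ∞) with
P(y = 0) = exp(−lambda), lambda = mu^(2−p)/(phi (2−p)).  Two mean
structures are provided:

* **standard** (log-ratio-of-means):
  `log(mu_it / mu_i,t−1) = v_it' gamma + gamma_DD (mu_i,t−1/ȳ − 1) + eps_i`,
  with `eps_i ~ N(alpha + x_i' beta, sigma²)` (hierarchical centering),
  data-augmented pre-survey means `mu_i0 ~ U[0,200]`, and optional
  negative density dependence;
* **change–change**: log abundance regressed on the log ratio of each
  covariate to its value in the site's first observed year.

Covariate inclusion is decided by reversible-jump MCMC; evidence is
summarized by Bayes factors (BF > 3 = positive evidence, printed `>10`
above 10).  Goodness of fit uses the posterior-predictive Bayesian
p-value with the dispersion-scaled Tweedie deviance as discrepancy
(rejection outside [0.025, 0.975]).  A synthetic-panel generator with
known truth (site turnover, habitat mix, trending predator counts,
AR(1) frost) makes every stage testable.

See the vignette `vignettes/tweedie-panel-models.Rmd` for the full model
account, priors, sampler design and known limitations.

## Worked example

```r
library(tweedpanel)

# a synthetic survey: 60 active sites, 15 winters, 8% turnover, a known
# negative predator effect (-0.05 on the normalized scale)
tr  <- synthetic_truth(n_site = 60, T = 15, seed = 42, gamma_dd = 0)
sim <- simulate_panel(tr)
fit <- fit_species(sim$panel, "standard",
                   chain_config(n_iter = 4000, n_burn = 1500, seed = 1),
                   spec = model_spec("standard",
                                     include_density_dependence = FALSE),
                   species = "synthetic-prey")
print(fit$summary)
print(fit$gof)
```

```
Posterior summary (standard formulation, 2500 draws)

Covariates (model-averaged; BF > 3 flagged):
          name posterior_mean inclusion_probability bayes_factor significant
      northing        -0.0010                0.1248       0.1426       FALSE
       easting        -0.0035                0.2420       0.3193       FALSE
       habitat        -0.0014                0.1404       0.1633       FALSE
   sparrowhawk        -0.0462                1.0000          >10        TRUE
 collared_dove         0.0178                0.7932        3.836        TRUE
    frost_days         0.0057                0.2892       0.4069       FALSE

Always-present parameters:
   name posterior_mean   lower   upper
  alpha        -0.0326 -0.0529 -0.0136
 sigma2         0.0060  0.0041  0.0086
    phi         0.4067  0.2876  0.5655
      p         1.3870  1.2697  1.4967
Bayesian p-value: 0.5480 (500 draws)
```

Reading the output: the predator covariate is decisively selected
(posterior inclusion 1, Bayes factor > 10) with a clearly negative
model-averaged coefficient near the generating −0.05; the pseudo-predator
control (true effect +0.01) is picked up with positive evidence; the
three site covariates, whose true effects are a few thousandths, are
correctly left out (BF well under 3); and the Bayesian p-value sits
mid-interval — no evidence of misfit.  The dispersion and index recover
the generating (0.5, 1.3) within their intervals.  Converting the
predator effect to the field's reporting scale:

```r
sd_hawk <- fit$scaling$sd[fit$scaling$name == "sparrowhawk"]  # 1.2266
percent_change_per_unit(per_unit_coef(-0.0462, sd_hawk))
#> [1] 3.7    # ~3.7% fewer birds per additional predator counted
percent_change_per_unit(-0.0369)
#> [1] 3.62   # the published House Sparrow coefficient: a 3.6% reduction
percent_change_on_doubling(-0.0325)
#> [1] 2.23   # change-model coefficient: 2.2% reduction per doubling
```

`risk_correlation()` correlates per-species predator coefficients with
user-supplied relative predation risks and reports the fitted line and
its value at zero risk.  A thin CLI over these functions is installed at
`inst/scripts/tweedpanel` (subcommands `simulate`, `fit`, `effects`,
`riskcorr`).

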