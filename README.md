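# phagecommons

Tools for a question at the intersection of phage therapy and evolutionary
biology: **can a phage engineered to secrete a biofilm-degrading enzyme
keep its transgene?** The enzyme (a dispersin) is released at lysis and
acts extracellularly, so it frees matrix-protected bacteria for *every*
phage nearby — wild competitors included. If carrying the gene costs
anything (say, a smaller burst size), the producer subsidizes its
competitors and can be driven extinct: a tragedy of the commons. The
package is aimed at researchers who want to simulate that dynamic and at
experimentalists who need rigorous frequency estimates for a transgene
from pooled-plaque PCR screens.

It has two halves:

**1. A delayed-lysis chemostat model.** Seven coupled equations track free
bacteria *B*, refuge bacteria *R*, GM and wild phage *P<sub>G</sub>*,
*P<sub>W</sub>*, infected cells *I<sub>G</sub>*, *I<sub>W</sub>*, and
enzyme *E*. Growth is logistic in *B + R* with capacity *C*; adsorption is
mass-action (*k*); washout (*w*) removes everything planktonic; lysis
happens *L* minutes after infection with survival factor e<sup>−wL</sup>,
releasing *b* progeny (and *Z* enzyme units per GM lysis). Refuge bacteria
leak into the susceptible state at the enzyme-dependent rate

&nbsp;&nbsp;&nbsp;&nbsp;h(E) = h<sub>max</sub> / (1 + s·d<sup>E</sup>),

which rises from 0.01/min at *E* = 0 to h<sub>max</sub> = 0.2/min as
enzyme accumulates. Integration is fixed-step Euler (dt = 10⁻³ min) with
a ring-buffer delay lookup, implemented in compiled code; runs are
bit-reproducible.

**2. Pooled-assay inference.** When *n* plaque isolates are pooled into
one PCR, a reaction is all-negative, all-positive, or mixed with
probabilities U<sup>n</sup>, T<sup>n</sup>, 1 − U<sup>n</sup> −
T<sup>n</sup> (*T* = transgene frequency, *U* = 1 − *T*). From *X*, *Y*,
*Z* reactions of each class the likelihood is the multinomial kernel
A<sup>X</sup>B<sup>Y</sup>C<sup>Z</sup>; the package returns the MLE and
the equal-tail 95% Bayesian credible interval from the normalized
likelihood under a flat prior, plus a χ² test of frequency change and
seeded synthetic-data generators for parameter-recovery validation.

## Worked example

Compete the enzyme producer (burst 17) against the wild phage (burst 20)
from equal starting frequencies, then estimate a transgene frequency from
a pooled screen:

```r
library(phagecommons)

traj <- run_scenario("gm_lower_burst")
summarize_competition(traj)
#>   initial_gm_frequency final_gm_frequency min_total_bacteria
#> 1                  0.5       9.167313e-08           140582.5
#>   t_min_total_bacteria peak_release_rate t_peak_release_rate clamp_events
#> 1                  155               0.2                  56            0
#>             outcome
#> 1 gm_lost_declining
```

Reading the row: both phages start at frequency 0.5; by 1500 minutes the
GM phage is effectively gone (~10⁻⁷) even though *its* enzyme did the
work — the release rate saturated at 0.2/min by minute 56 and total
bacteria collapsed from 5×10⁸ to ~1.4×10⁵ per mL by minute 155. That is
the tragedy: the producer pays the burst-size cost, everyone shares the
freed hosts. Swap the bursts (`"gm_higher_burst"`) and the outcome label
flips to `gm_winning`.

```r
estimate_frequency(assay_counts(10, X = 6))   # 60 plaques, none positive
#> Transgene frequency estimate from 6 pooled reactions (60 plaques)
#>   T_hat = 0, 95% credible interval (0.00, 0.06)
```

Sixty unanimously negative plaques give a point estimate of 0 but still
leave a 95% upper bound of 0.06 — the screen cannot exclude a ~6%
residual frequency. Validate the estimator at a known truth:

```r
recovery_experiment(0.26, n = 10, R = 6, reps = 1000, seed = 1)
#>   T_true  n R reps      bias      rmse coverage
#> 1   0.26 10 6 1000 0.1487837 0.2126144    0.997
```

Coverage is near-nominal, but six 10-plaque pools at T = 0.26 are usually
all mixed, so the MLE is biased toward 0.5 at this depth — increase `R`
and the bias and RMSE fall (tested over R = 6, 24, 96).

## Learning more

The methods vignette (`vignettes/phagecommons-methods.Rmd`) documents the
model equations and their assumptions, the numerical choices (step size,
clamping, history initialization, posterior grid), the design decisions,
and what the synthetic-data checks do and do not establish about real
assay data.
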