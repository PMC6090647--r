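# propiokin

Kinetic modelling of propionic acid (PA) fermentation by
*Propionibacterium acidipropionici*, for bioprocess engineers and
quantitative microbiologists who need to simulate batch and fed-batch
cultures, fit kinetic parameters to time-course data, design feeding
strategies, and compute standard fermentation performance metrics.

## The model

The package implements a non-structured kinetic model on six states —
biomass X, sucrose S, and the organic acids PA, pyruvate (PYR), acetate
(AA) and succinate (SA), all in g/L. Substrate uptake is Monod in sucrose
with hyperbolic product inhibition by PA and AA:

    qs = rs_max · S/(Ks + S) · kipa/(kipa + PA) · kiaa/(kiaa + AA)
    µ  = qs·Yxs − ms·Yxs

and each acid follows a Luedeking–Piret law with a growth-associated
coefficient K and a non-growth-associated rate β; pyruvate is additionally
drained through a saturable term PYR/(PYR + K_pyr) that feeds acetate and
succinate:

    dX/dt   = µX                         dS/dt   = −qs·X
    dPA/dt  = (K1·µ + β_pa)·X            dPYR/dt = (K2·µ + β_pyr − K3·f)·X
    dAA/dt  = (K4·µ + β_aa + K5·f)·X     dSA/dt  = (K6·µ + β_sa + K7·f)·X

with f = PYR/(PYR + K_pyr). In fed-batch mode a feed of rate F(t) (L/h)
and sucrose concentration So adds dV/dt = F and a dilution rate D = F/V
that dilutes every broth component while delivering D·(So − S) of sucrose.

Model reliability is quantified by the per-variable averaged coefficient
of determination, R² = (1/m) Σ_j (1 − SSE_j/SST_j). Parameter estimation
is two-stage: Ks from Monod rate-vs-substrate data (`fit_monod_ks()`),
then the remaining parameters by bounded Levenberg–Marquardt least squares
on max-scaled residuals (`fit_parameters()`). `design_constant_feed()`
searches constant-rate feeding strategies that maximise final PA subject
to a sucrose path constraint (default ceiling 40 g/L).

## Worked example

Simulate the bundled high-producer (wgs7-like) batch scenario — 80 g/L
initial sucrose, 0.075 g DCW/L inoculum — and summarise its performance:

```r
library(propiokin)
sc <- reference_scenario("wgs7", "batch")
ts <- simulate_fermentation(sc$initial, sc$parameters, seq(0, 100, 4))
fermentation_summary(ts)
#> Fermentation performance summary:
#>   mu       0.2768 1/h (mid-exponential)
#>   Yps      0.580 g/g
#>   PA:AA    5.51 g/g
#>   PA:SA    6.24 g/g
#>   Pv       0.945 g/L/h over 15-30 h
#>   qs       1.071 g/gDCW/h
#>   qp       0.382 g/gDCW/h
#>   final PA 46.36 g/L
```

The run converts 80 g/L sucrose into 46.4 g/L PA at a yield of
0.58 g PA per g sucrose, with 5.5 g of PA per g of acetate by-product and
a 15–30 h volumetric productivity of 0.95 g/L/h.

Fit the identifiable kinetic parameters to a noisy synthetic time course
shipped with the package (5 % multiplicative measurement noise):

```r
obs <- read_timeseries_csv(system.file("extdata", "wgs7_batch_synthetic.csv",
                                       package = "propiokin"))
free <- c("rs_max", "Yxs", "K1", "beta_pa")
guess <- reference_parameters("wgs7")
guess[free] <- guess[free] * 1.3          # deliberately wrong start
fit <- fit_parameters(obs, structure(guess, class = "kinetic_parameters"),
                      fixed = setdiff(kinetic_parameter_names(), free))
fit
#> Kinetic model fit: 156 observations, converged: TRUE
#>   weighted SSE 0.6926, aggregate R-squared 0.9513
#>   per-variable R-squared:
#>   X_gL   S_gL  PA_gL PYR_gL  AA_gL  SA_gL
#> 0.9830 0.9933 0.9888 0.7685 0.9782 0.9958
#>   free parameters:
#>  rs_max     Yxs      K1 beta_pa
#> 1.37367 0.25322 1.18892 0.04507
```

The fit recovers K1 and β_pa essentially exactly (truth 1.1939 and 0.045)
and rs_max/Yxs to within the noise level, with an averaged R² of 0.95
against the noisy observations.

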