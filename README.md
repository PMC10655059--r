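# csmigrate

Compartment modelling of long-term caesium-137 vertical migration in soil.

After a fallout event, ¹³⁷Cs deposited at the surface migrates slowly down
the soil column. For a column sampled in six 5-cm slices to 30 cm, the
observable is the fractional contribution of each layer,
`R_z = A_z / T` with `A_z` the layer's mass activity (Bq/kg) and `T` the sum
over the six layers. `csmigrate` is for radioecologists running (or
re-analysing) multi-decade soil-profile monitoring campaigns: it provides
the profile arithmetic (fractions, decay backdating, areal deposition), a
six-compartment catenary chain model for the time evolution of the
fractions, estimation of the single transfer rate from the surface layer,
and a synthetic-data generator so the whole pipeline is testable when the
measurement series itself is not public.

## The model

Each layer is a compartment; activity flows only into the next-deeper
compartment at a first-order rate `k` (1/y), and the deepest compartment
leaks below the sampled column:

    dR5/dt  = -k R5
    dRz/dt  =  k R(z-5) - k Rz        z = 10, ..., 30

Because the `R_z` are ratios of same-date activities, radioactive decay
cancels and does not appear. With equal rates the closed form is a
polynomial times `exp(-kt)` (the repeated-eigenvalue solution); with
distinct rates the Bateman-type product form applies, e.g. for the second
compartment

    R10(t) = k1 R5(0) / (k2 - k1) * (exp(-k1 t) - exp(-k2 t)) + R10(0) exp(-k2 t).

Only `k` is fitted, from the surface layer with the intercept fixed at its
accident-date value `R5(0) = 0.71`; deeper layers are then predicted with
no further freedom. From `k` follow the mean residence time `1/k` and the
mean vertical migration velocity `thickness * k`. An increasing-rate
variant (faster second link, the diffusion-dominated signature) is
implemented so the equal-rate assumption can be tested by RSS ranking
rather than assumed.

## Worked example

```r
library(csmigrate)

# a measured-style profile: Bq/kg in six 5-cm layers
p <- soil_profile("2023-04-15", c(50, 20, 10, 10, 5, 5), density = 1.3)
fractional_contributions(p)$r
#>   R5  R10  R15  R20  R25  R30
#> 0.50 0.20 0.10 0.10 0.05 0.05
total_deposition(p, backdated = TRUE)   # kBq/m2 at the accident date
#> [1] 15.2366

# propagate the equal-rate chain from the accident-date state
m <- chain_model(0.024)                  # rates in 1/y
round(equal_rate_solution(m, 37)$r, 3)
#>    R5   R10   R15   R20   R25   R30
#> 0.292 0.305 0.180 0.094 0.057 0.036

residence_time(0.024)        # 41.66667 y in the 0-5 cm layer
migration_velocity(0.024)    # 0.12 cm/y for 5-cm layers

# fit k back from a synthetic campaign at the study design
cfg <- synthetic_config()                # k = 0.024, CV 10%, 24 campaigns
sim <- simulate_fraction_series(cfg, seed = 7)
fit_k(sim$t_years, sim$R5)
#> <fit_result> k = 0.0218 +/- 0.0007 1/y (n = 24, RSS = 0.017569)
#>   fixed-intercept 1-parameter ordinary LS, asymptotic SE, R5(0) fixed at 0.71
```

After 37 years the surface and second layers hold nearly equal fractions
(0.29 vs 0.30) — the front of the activity distribution has moved one layer
down — and the single-seed fit lands within the ±0.006 band of the
generating 0.024 1/y (over 200 seeds the mean recovery is unbiased; see
`analysis/06_parameter_recovery.R`).

The numbered scripts under `analysis/` run the full study: `01_simulate.R`
writes a synthetic campaign, `02_fractions_deposition.R` the fraction and
deposition tables, `03_fit_transfer_rate.R` the rate fit and derived
quantities, `04_predict_curves.R` the model curves, `05_compare_rate_models.R`
the equal-rate vs increasing-rate ranking, and `06_parameter_recovery.R` a
200-replicate recovery study. Each writes its tables under `results/` with
a provenance header (seed and configuration).

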