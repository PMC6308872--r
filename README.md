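# coldrange

Metabolic constraints on the cold (poleward) range boundaries of endotherms.

## The problem

Why do bird and mammal ranges stop where they do toward the poles?  One
mechanistic hypothesis is energetic: below the thermal neutral zone an
endotherm must raise its resting metabolic rate in proportion to how far the
ambient temperature falls below its lower critical temperature, and there is
a limit to how far metabolism can be elevated above basal levels.  If that
limit binds, cold range edges should track thermal isoclines, the
interspecific distribution of the required elevation factor should be
strongly peaked, and range edges should shift poleward with warming in a
predictable way.

`coldrange` is for macroecologists and ecophysiologists who want to test
and apply this idea: it turns physiology tables, species presence grids and
temperature rasters into per-species metabolic expansibility estimates,
distribution-shape inference, trait regressions, and thermal-isocline range
projections.

## The model

For a species with basal metabolic rate `BMR` (ml O2 h^-1), set-point body
temperature `T_b` and lower critical temperature `T_lc` (degC), minimum
thermal conductance is the slope of the Scholander-Irving line through
(`T_lc`, `BMR`) and (`T_b`, 0):

    C = BMR / (T_b - T_lc)                      [ml O2 h^-1 degC^-1]

With `T_min` the median minimum temperature of the cells along the species'
cold range boundary, the resting metabolic rate required at the boundary
and the metabolic expansibility there are

    MR_CRB = (T_lc - T_min) C + BMR             (for T_min < T_lc)
    ME_CRB = MR_CRB / BMR

Inverting the model gives the predicted lower thermal limit for a target
expansibility, the basis of the range projections:

    T_limit = T_lc - (ME - 1) BMR / C

Rates reported in watts are converted with 179 ml O2 h^-1 W^-1 (lipid
metabolism).  Around this core the package provides:

* per-longitude extraction of poleward/equatorward boundary cells and
  median/SD/mad summaries of boundary temperatures;
* distribution shape inference for ME: kernel-density peaks with twin-peak
  averaging, the D'Agostino skewness test, the Bonett-Seier kurtosis test
  on Geary's metric, Hartigan's dip test with Monte Carlo p-values, and a
  randomization null that shuffles boundary temperatures across species;
* trait regressions with exhaustive AICc subset selection and model
  averaging;
* projection of current and future cold range boundaries: strict
  habitability masking at `T_limit`, connected-component clump labelling,
  removal of clumps smaller than 5% of the largest, restriction to the
  observed range envelope, median cold-edge latitude, and poleward-positive
  shifts;
* a seeded synthetic-world generator with known ground truth for
  end-to-end validation.

## Worked example

A synthetic world with 100 species whose range edges track their own
thermal isoclines (true torpor effect +1.5, true mass effect -0.5 per
log10 g, +2 degC of uniform warming on a 0.5 degC/degree gradient):

```r
library(coldrange)

spec  <- synthetic_world_spec(n_species = 100, seed = 1)
world <- make_world(spec)
res <- analyze_cohort(normalize_physiology(world$physiology),
                      transform(world$traits, log10_mass = log10(mass_g)),
                      world$masks, world$climate$current, world$climate$future,
                      n_reps = 1000, dip_reps = 500, seed = 1, quiet = TRUE)

me_distribution_summary(res$species$me_crb, seed = 2)
#> ME distribution (n = 100)
#>   peak 3.731  median 3.886  mean 3.940 (sd 1.068)
#>   skewness 0.403 (z = 1.70, p = 0.0893)
#>   Geary kurtosis 0.813 (z = -0.49, p = 0.621)
#>   dip D = 0.0215 (p = 0.998)
```

The distribution of recovered expansibility is unimodal (dip p = 0.998)
and right-skewed, as built into the generator.  Shuffling boundary
temperatures across species breaks the isocline-tracking structure, so the
observed mean falls outside the randomization null:

```r
nm <- randomization_null(res$species, res$species$t_min, "mean", seed = 3)
#> null mean interval: [4.10, 4.25], observed 3.94
```

The trait model recovers the built-in effects (truth: torpor +1.5, mass
-0.5), and the projected cold-edge shift matches the isocline displacement
`2 degC / 0.5 degC per degree = 4 degrees`:

```r
res$trait_models$full$coefficients
#>         term estimate     se     t        p
#>   log10_mass   -0.341 0.0991 -3.44 8.74e-04
#>       torpor    1.578 0.1952  8.08 2.41e-12

mean(res$projections$shift_deg, na.rm = TRUE)
#> [1] 3.925
```

For file-based workflows, `write_world()` emits the CSV/ASCII-grid inputs
consumed by `run_pipeline(pipeline_config(...))`, which writes per-species
tables, summary JSON, an exclusion log and a reproducibility manifest.

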