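# domlake

Toolkit for quantifying the microbial biodegradation of dissolved organic
matter (DOM) in lakes, from bulk carbon to single molecular formulas. It is
aimed at aquatic biogeochemists running bottle-incubation experiments who
need, in one place:

* **Two-pool decay kinetics** for DOC / CDOM time series — the degraded
  fraction `y(t) = fa(1 − e^(−k1 t)) + fb(1 − e^(−k2 t))` with readily
  (`fa`, `k1`) and slowly (`fb`, `k2`) biodegradable pools, half-lives
  `ln2/k`, the refractory fraction `fc = 1 − y(t_end)`, and adjusted R².
* **FT-ICR MS formula handling** — [M−H]⁻ peak-to-formula assignment under
  a ppm tolerance, elemental (CHO/CHON/CHOS/CHONS) and van Krevelen
  compound classes (seven O/C × H/C windows), CRAM identification by
  DBE/C, DBE/H, DBE/O windows, class profiles, Jaccard similarity of
  formula sets, and consumed/produced/resistant molecule fate tracking.
* **EEM-PARAFAC** — nonnegative trilinear decomposition of fluorescence
  excitation–emission matrices by alternating least squares, split-half
  validation with Tucker congruence (plus a degenerate-split rejection),
  leverage-based outlier flagging, matching against reference components
  (default library: C1 330/422, C2 260,360/450, C3 320,390/500, C4
  280/400, C5 275/305,340 nm), Fmax scores, and the a254 CDOM absorption
  coefficient.
* **Community ecology** — Shannon diversity, Bray–Curtis, principal
  coordinates, and an abundance-filtered Spearman screen linking DOM
  features to OTUs with BH-adjusted p-values.
* **Seeded synthetic-data generators** for all of the above, so the whole
  pipeline is testable end-to-end without instrument data.

## Worked example

Simulate a 60-day algal-DOM incubation from its kinetic preset (readily
fraction 53.8 %, slow-pool half-life 49.51 days), refit it, and read the
pools back:

```r
library(domlake)

profile <- source_profile("DOMa")
series  <- gen_decay_series(profile, noise_sd = 0.002, seed = 42)[[1]]
fit     <- fit_two_pool(series, seed = 42)
fit
#> two-pool biodegradation fit
#>   fa = 0.543 (t1/2 fast 1.53 d), fb = 0.378 (t1/2 slow 63.73 d)
#>   fc = 0.275, adj R^2 = 1, converged: TRUE
```

`fa = 0.543` says ~54 % of the initial DOC is consumed within days
(half-life ~1.5 d); the slowly biodegradable pool (`fb`) turns over on a
~60-day scale (weakly identified from a single noisy 60-day replicate —
the acceptance suite shows the median over 200 replicates lands on the
generating 49.51 d); `fc = 0.275` of the carbon is still there when the
incubation ends at day 60.

Molecular fate between two time points:

```r
t0   <- gen_formula_table(400, seed = 1)                  # ~80% lignins
plan <- list(consume = c(proteins = 1), produce = c(lignins = 0.3),
             cram_quota = 0.5)
days <- gen_biodegradation_series(t0, plan, days = c(0, 5, 60), seed = 2)
molecule_fate(days[["0"]], days[["60"]])
#> fate_table: 495 formulas (34 consumed, 95 produced, 366 resistant)
#>   class share change (pp): lipids -0.07, proteins -7.18, lignins +7.79, ...
```

Proteins are consumed, lignin-region molecules (half of them CRAMs here)
are produced, and the per-class intensity-share changes sum to zero.

PARAFAC on a five-component synthetic stack:

```r
stack <- gen_eem_stack(40, noise_frac = 0.01, seed = 7)
split_half_validate(stack, seed = 7)$selected_k
#> [1] 5
model <- parafac_als(stack, 5, n_starts = 4, seed = 7)
match_components(model)[, c("component", "reference", "congruence", "matched")]
#>   component reference congruence matched
#> 1         1        C1  0.9999998    TRUE
#> 2         2        C2  0.9999999    TRUE
#> 3         3        C5  0.9999995    TRUE
#> 4         4        C4  0.9999993    TRUE
#> 5         5        C3  0.9999999    TRUE
```

## Command line

An executable script ships in `inst/exec/domlake`:

```sh
domlake annotate --peaks peaks.csv --tolerance-ppm 1.0 --out table.csv
domlake kinetics --series decay.csv --n-starts 16 --seed 7 --out fit.json
domlake parafac  --manifest eems.csv --k-range 2 7 --threshold 0.95 --seed 7 --out model.json
domlake compare  --tables a.csv b.csv --variant as_printed
domlake ecology  --otus otus.tsv --dom-features feats.csv --min-abundance 0.001
domlake simulate decay|ftms|eem|otu --preset DOMa --seed 7 --out dir/
domlake run      --config pipeline.json
```

Exit codes: 0 success, 2 validation error, 1 stage failure.

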