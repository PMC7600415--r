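# caprihap

Lactation-curve modelling and casein-complex haplotype association for
dairy-goat test-day records.

Milk recording in goats produces a handful of monthly controls per
lactation: daily milk yield (kg), fat / protein / dry matter / lactose
(%), and somatic cell count (SCC, ×10³ cells/mL). `caprihap` turns such
records into haplotype-association results:

1. **Records → lactations.** Validated test-day records are grouped into
   per-lactation series and total yield is standardized to 210 days in
   milk with the Fleischmann interval rule
   `Y₂₁₀ = M₁t₁ + Σ ((Mᵢ+Mᵢ₊₁)/2)(tᵢ₊₁−tᵢ) + M_m(210−t_m)`.
2. **Lactation curves.** A registry of classical models — Ali–Schaeffer
   `y(t) = b₀ + b₁x + b₂x² + b₃ln(1/x) + b₄ln²(1/x)` (x = t/T) for milk
   and components, parabolic yield-density `y(t) = 1/(b₀ + b₁t + b₂t²)`
   for SCC, plus Wood, Wilmink, quadratic, inverse quadratic, mixed-log —
   fitted per lactation by multi-start damped least squares
   (Levenberg–Marquardt, relative-RSS tolerance 10⁻⁸, ≤ 2000 iterations),
   with RSS / MSPE / adjusted R² / AIC / AICc / BIC / Durbin–Watson /
   Shapiro–Francia selection criteria and rank-sum model ranking.
3. **Curve shapes.** Peak and persistency per fitted curve: Ali–Schaeffer
   peak = b₀, persistency = (b₁, b₂); parabolic yield-density peak =
   −b₁/(2b₂), persistency = 2b₀·Days + b₁.
4. **Haplotypes.** Token-delimited phased assignments over the casein loci
   (CSN1S1, CSN1S2, CSN2, CSN3; alleles include the deletion token `.-`
   and multi-base insertions such as `AATC`), minor allele frequency with
   the 0.05 rare-variant flag, observed heterozygosity, pairwise LD
   (D′ = |D|/D_max, r² = D²/(p_A p_a p_B p_b)), and grouping of animals by
   carried haplotype variant.
5. **Association.** One-way ANOVA per trait × parameter across haplotype
   groups: definitional SS/df/MS/F/p, the JZS Bayes factor
   `BF₁₀ = ∫ (1+g)^((N−1−p)/2) [1+g(1−R²)]^(−(N−1)/2) π(g) dg` with
   g ~ InvGamma(1/2, Nr²/2) and r = 1 evaluated by quadrature, and
   per-group posterior deviations from the grand mean with 95% credible
   intervals (significant ⇔ 0 outside the interval).

A synthetic herd generator (`sim_config()` / `simulate_herd()`) with known
ground truth — 159 goats, 28 farms, ~3.91 lactations per goat, 5 controls
per lactation from ~day 21 at 4–6-week intervals — makes the whole
pipeline testable without access to raw milk-recording archives. See the
methods vignette (`vignettes/lactation-haplotype-analysis.Rmd`) for the
models, assumptions, defaults and limitations.

## Worked example

Simulate a 60-goat herd in which haplotype HapB adds 0.4 kg/day to the
milk curve level per copy, then test the haplotype effect on standardized
210-day yield among homozygous carriers:

```r
library(caprihap)

cfg <- sim_config(n_goats = 60, n_farms = 12,
                  haplotype_freqs = c(HapA = 0.55, HapB = 0.45),
                  effect_sizes = list(HapB = c(milk_kg = 0.4)),
                  seed = 42)
ds   <- simulate_herd(cfg)
lact <- build_lactations(ds$records)
lact[[1]]
#> <lactation_series G0001 lact 1: 5 controls, d1 = 23, 210-d milk = 560.2 kg>

grp <- group_by_haplotype(ds$assignments, homozygous_only = TRUE)
str(grp$summary)
#> List of 3
#>  $ n_animals            : int 60
#>  $ n_haplotypes         : int 2
#>  $ animals_per_haplotype: num 30

yt  <- lactation_table(lact)
map <- setNames(rep(names(grp$groups), lengths(grp$groups)),
                unlist(grp$groups, use.names = FALSE))
g   <- map[yt$animal_id]
res <- haplotype_anova(yt$yield210_milk_kg[!is.na(g)], g[!is.na(g)],
                       trait = "milk_kg", parameter = "yield210")
res
#> <haplotype_anova milk_kg / yield210>
#>   Between: SS = 728225.807, df = 1, MS = 728225.807
#>   Within:  SS = 96451.288, df = 102, MS = 945.601
#>   F = 770.120, p = 2.468e-49, BF10 = 9.328e+45
print(res$posteriors, digits = 4)
#>   group  n  mean deviation post_sd ci_lower ci_upper significant
#> 1   H01 49 707.9     88.65   3.226    82.32    94.99        TRUE
#> 2   H02 55 540.2    -78.98   2.874   -84.63   -73.34        TRUE
```

Reading the output: the two homozygote groups differ by 707.9 − 540.2 ≈
168 kg of 210-day yield — matching the planted effect (2 copies × 0.4
kg/day × 210 d = 168 kg) — with an enormous F and Bayes factor, and both
group deviations exclude zero. `grp$haplotypes` maps the `H01`/`H02`
labels back to their token sequences.

The full pipeline (fit → shapes → grouping → ANOVA for all six traits) is
one call:

```r
run <- run_pipeline(pipeline_config(simulate = cfg, out_dir = "out", seed = 42))
head(run$anova)        # Between/Within rows: SS, df, MS, F, p, BF10
```

or, from a shell:

```sh
Rscript inst/cli/caprihap.R simulate --out demo --seed 3 --goats 20
Rscript inst/cli/caprihap.R run --records demo/records.csv \
        --haplotypes demo/haplotypes.csv --out demo_results --seed 3
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from
scratch: it simulates the default 159-goat herd from the given seed,
executes the full reproduction pipeline (standardize → fit the pinned
model pair → curve shapes → haplotype grouping → ANOVA with Bayes
factors), writes the report tables under `<out dir>/pipeline/`, and
emits the JSON report to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
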