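# idasense

Modelling and chemometrics for colorimetric saccharide sensing with an
**indicator displacement assay (IDA)**.

A boronic acid receptor (the *host*, e.g. 3-nitrophenylboronic acid) binds
catechol dyes (the *indicators*: alizarin red S, bromopyrogallol red,
pyrogallol red, pyrocatechol violet) as boronate esters, changing their
colour. Saccharide *guests* compete for the host and displace the dye,
recovering its free-dye colour. Because each dye/sugar combination has its
own affinity, a panel of four dye channels produces a cross-reactive
fingerprint from which monosaccharides (fructose, glucose, galactose,
xylose, mannose, rhamnose, *N*-acetylglucosamine) can be identified and
quantified — no custom synthesis, just pattern recognition on mixtures of
off-the-shelf reagents.

## The model

For totals $[H]_t$, $[I]_t$, $[G]_t$ and 1:1 complexes HI and HG, the free
host concentration $[H]$ solves the mass balance

$$[H]_t = [H] + \frac{K_G[H]}{1+K_G[H]}[G]_t + \frac{K_I[H]}{1+K_I[H]}[I]_t ,$$

and the absorbance at a dye's observation wavelength is

$$A = \frac{[I]_t}{1+K_I[H]}\left(\varepsilon_I b + \varepsilon_{HI} b K_I [H]\right),$$

with $K_I, K_G$ the host–indicator and host–guest association constants
(M⁻¹) and $\varepsilon_I, \varepsilon_{HI}$ the molar absorptivities of
free and host-bound dye. The left side of the balance is strictly
increasing in $[H]$, so the package brackets the unique root on
$[0,[H]_t]$ and solves it with Brent's method. Binding constants are
estimated by nonlinear least squares against this forward model: $K_I$
(with $\varepsilon_{HI}$) from dye⇐host titrations, then $K_G$ from guest
titrations of the preformed ensemble with $K_I$ held fixed. Estimates
below 10 M⁻¹ are reported as bounds ("< 10"), since such weak binding
barely perturbs the speciation.

The array pipeline mirrors the 384-well protocol: 24 replicate wells per
condition, fixed-count exclusion of the 4 most extreme wells (iterative
studentized deviation), one-way ANOVA ranking of the dye channels, Fisher
LDA with leave-one-out (jackknife) validation, and — for binary
fructose/glucose mixtures — PCA (3 components) followed by per-sugar
support-vector regression.

## Worked example

```r
library(idasense)

# one full synthetic plate: 4 channels x (control + 7 sugars) x 24 wells
design <- array_design(seed = 1)
plate  <- generate_plate(design)

rmx  <- build_response_matrix(plate, n_exclude = 4)   # 24 -> 20 per condition
rate <- jackknife_classification_rate(rmx)
anova_contribution(rmx)
```

```
response matrix: 160 observations x 4 channels, 8 classes
 channel         F       p_value degenerate rank
     BPR 17101.558 1.106227e-216      FALSE    1
     ARS 12837.737 3.126667e-207      FALSE    2
      PV 11954.402 6.979711e-205      FALSE    3
      PR  9490.449 2.793325e-197      FALSE    4
jackknife (leave-one-out) classification rate: 100.00 %
```

All 160 held-out observations are assigned to the correct analyte; BPR is
the channel contributing most to the discrimination, and the fructose
cluster sits farthest from the control (it is the strongest binder in
every channel). The numbered scripts under `analysis/` run the complete
study — plate simulation, binding-constant fitting (e.g. the noiseless
BPR/fructose round trip returns K_G = 1900.00 M⁻¹, and five 2%-noise
replicate fits spread by 6.5%), the qualitative LDA above, the
semi-quantitative 0–100 mM concentration series (100% rate, perfectly
monotone LD1 trend) and the mixture regression (held-out RMSE ≈ 2.5 mM
for both sugars over a 70 mM range) — writing tables to `results/`.

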