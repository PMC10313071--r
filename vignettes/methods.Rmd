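---
title: "Methods: from headspace vials to annual N2O emission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from headspace vials to annual N2O emission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denitflux)
```

This vignette is the package's account of its science: the models behind
each stage, the parameters that matter, the numerical choices, and what the
synthetic-data tests do and do not demonstrate about real measurements.

## Dissolved-gas chemistry

A water sample sealed in a vial has part of its volume replaced with He and
is shaken to gas–liquid equilibrium. Writing $C_G$ for the measured
headspace concentration, the original dissolved concentration follows from
mass conservation: the gas now in the headspace ($C_G V_G$) plus the gas
still dissolved at equilibrium ($C_G K_0 R T \cdot V_L$, Henry's law) must
equal what was dissolved before replacement, so

$$C_L = C_G\,(K_0 R T + V_G/V_L).$$

$K_0$ is the Weiss–Price N$_2$O solubility polynomial,
$\ln K = A_1 + A_2(100/T) + A_3\ln(T/100)\,[+A_4(T/100)^2] +
S\,(B_1 + B_2(T/100) + B_3(T/100)^2)$, strictly decreasing in temperature
and salinity over its 0–40 °C fit range (the package warns outside it).

Two coefficient sets are carried, because two different physical questions
are asked of the solubility:

* **dry** — the Henry constant against dry-gas partial pressure. This is
  the correct constant inside the vial mass balance, where the headspace
  reading is a molar concentration of the actual gas phase.
* **moist** — the equilibrium function for water in contact with
  water-vapor-saturated air at 1 atm total pressure. This is the correct
  function for the air-equilibrium concentration
  $C_{eq} = F(T,S)\,x_{N_2O}P$ of surface water under a real atmosphere,
  and it is the default for `equilibrium_concentration()`. The two differ
  by roughly 5 % at 30–37 °C (the vapor-pressure correction), which is
  material: the excess concentrations computed from field observations
  close on the observed values only with the moist-air form, which is why
  the package defaults to it rather than ignoring the distinction.

$\Delta N_2O = C_L - C_{eq}$ and saturation $= 100\,C_L/C_{eq}$ follow
directly; $\Delta > 0$ if and only if saturation exceeds 100 %. The flux is
$F = K\,\Delta N_2O$, exact in units because 1 nmol L$^{-1}$ equals
1 µmol m$^{-3}$ and $K$ is in m d$^{-1}$.

The atmospheric mole fraction defaults to 331 ppb
(`ATM_N2O_MOLE_FRACTION`); it drifts upward ~0.25 %/yr and should be
overridden for other sampling dates.

**Gas transfer velocity.** Field studies rarely publish the exact
parameterization; the package therefore makes $K$ pluggable: a constant-k
passthrough (the default route when a flux is to be matched to an observed
value), the estuarine linear fit $k_{600} = 4.045 + 2.58\,U_{10}$ (cm/h),
and the quadratic $k_{600} = 0.31\,U_{10}^2$. Wind-based presets rescale by
$(Sc/600)^{-0.5}$ with the Wanninkhof N$_2$O Schmidt-number cubic,
interpolated linearly in salinity between the freshwater and salinity-35
fits; the $-0.5$ exponent (wavy, unbroken surface) is configurable.

## Isotope pairing

Spiking $^{15}$NO$_3^-$ (purity 0.996, 100 µmol L$^{-1}$ against a small
ambient pool) gives the nitrate pool a $^{15}$N fraction
$f_{15} = \text{purity}\cdot\text{added}/(\text{ambient}+\text{added})$.
If N$_2$ forms by random pairing of two N atoms from this pool, the
isotopologue proportions are binomial — $^{28}$N$_2$: $(1-f)^2$,
$^{29}$N$_2$: $2f(1-f)$, $^{30}$N$_2$: $f^2$ — so the expected
$^{29}$N$_2$ given an observed $^{30}$N$_2$ amount is
$D_{29} = P_{30}\cdot 2(1-f_{15})/f_{15}$.

A note on conventions: field write-ups sometimes define the pool fraction
as the $^{14}$N share, but the pairing formula is only consistent with the
binomial expectation when its fraction is read as $f_{15}$ — with the
$^{14}$N reading the predicted $^{29}/^{30}$ ratio would invert. The
package uses the $f_{15}$ reading by default and exposes the complement
convention behind `convention = "n14"` so either bookkeeping can be
reproduced. The property suite pins the default to a brute-force
Monte-Carlo pairing oracle at several labeling fractions.

Rates: $R_{N_2} = (D_{29} + 2P_{30})/\Delta t$ is the $^{15}$N-based N$_2$
production as conventionally reported; an optional $1/f_{15}^2$ factor
(`correct_total = TRUE`, off by default) estimates total denitrification
N$_2$ including unlabeled pairs. $R_{N_2O}$ is the linear N$_2$O
accumulation between $T_0$ and $T_2$ vials, converted to per-kg-soil via
the slurry volume over soil mass, times two N atoms per molecule — the ×2
lives in exactly one place to prevent double conversion. Rates are per kg
fresh soil (no dry-weight conversion is assumed). Replicate vials are
averaged per group; the replicate SD propagates to the rate by first-order
error propagation. Negative rates (net consumption) are preserved and
flagged, never clipped — silent clipping biases means. The end-product
ratio $100\,R_{N_2O}/(R_{N_2}+R_{N_2O})$ is scale-invariant and bounded in
[0, 100] for non-negative rates. Since both the measured $D_{29}$ and the
pairing prediction are legitimate inputs to $R_{N_2}$, `estimate_rates()`
offers both (`d29_source`); they coincide exactly on synthetic data
generated under random pairing.

## Annual upscaling

Soil: annual molar emission $=$ rate $/2 \times$ (depth $\times$ bulk
density) $\times$ 8760 h $\times 10^{-6}$; mass $=$ molar $\times$
44.013 g mol$^{-1}$. The bulk-density default (1.39 g cm$^{-3}$) is a
**reconstruction**: the estimation method behind the published annual soil
figure is not retrievable, so the default is chosen so that the printed
chain (0.51 µmol N kg$^{-1}$ h$^{-1}$ over 0.10 m → 0.31 mol →
13.67 g N$_2$O m$^{-2}$ yr$^{-1}$) closes, and it sits inside the normal
paddy-soil range (1.1–1.6 g cm$^{-3}$). It is a loud, overridable
parameter, not a certified field value. Water: flux × 365 d × $10^{-6}$;
no N-atom factor because the flux already counts N$_2$O molecules. The
year is 365 d / 8760 h with no leap handling, and rates are assumed
constant year-round — both assumptions inherent to this style of
annualized potential, not claims about seasonal dynamics.

## Gene diagnostics

**qPCR.** Standard curves are least-squares fits of Cq against
log$_{10}$ copies; efficiency $=100\,(10^{-1/\text{slope}}-1)$ with
acceptance gates 90–110 % and $R^2 \ge 0.97$. Quantification inverts the
curve and refuses gated-out curves unless explicitly overridden.
Abundance ratios (nirS/nirK, nosZ II/nosZ I, nir/nosZ with
nir = nirS + nirK, nosZ = clade I + II) index the genetic imbalance between
N$_2$O production and reduction capacity.

**Spearman correlations** between physiochemistry or gene abundance and
rates use an exact-permutation two-sided p-value for $n \le 9$ (full $n!$
enumeration; at the study-typical $n = 7$ that is 5040 permutations) and
the large-sample approximation otherwise. No multiple-testing correction
is applied, matching common practice for these small exploratory panels;
users testing many hypotheses should correct downstream.

**TPM profiling.** TPM$_i = (c_i/\ell_i)/\sum_j (c_j/\ell_j)\times 10^6$,
computed per sample over *all* ORFs in the table, not per gene subset —
normalizing at the annotation stage changes per-gene values and is the
documented choice here. nosZ ORFs are split into clades I/II by strict
majority over up to 10 reference hits; ties and empty lists are
`unassigned` and reported, never dropped (the tie rule is this package's
choice — no standard exists). Lineages lacking the aggregation rank pool
into the first-class bucket `"unclassified bacteria"`. The gene×taxon
matrix flags taxa with norB TPM $> 0$ whose summed nosZ TPM is below a
configurable fraction (default 0.1) of norB — the truncated-denitrifier
signature of candidate net N$_2$O producers.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the *structure* of the study conditions: seven
samples at 31.3–36.7 °C and salinity 2; dissolved N$_2$O spanning
~124–236 nmol L$^{-1}$; 12.5 mL vials with 5 mL He headspace; 1:7
weight:volume slurries in triplicate $T_0$/$T_2$ vials incubated 2 h; true
rates centred on $R_{N_2}$ = 24.63 ± 6.76 and $R_{N_2O}$ = 0.51 ± 0.20
µmol N kg$^{-1}$ h$^{-1}$; Proteobacteria-dominated napA/nirS communities
with a diverse nosZ II community. Noise models follow instrument behavior:
multiplicative log-normal for GC/MIMS concentrations (keeps values
positive), additive Gaussian for Cq, multinomial at the counts level for
metagenome reads. Default noise levels (3 % GC, 10 % MIMS, 0.1 Cq cycles)
are typical instrument precisions for these assays.

Passing the round-trip and recovery tests shows the estimators invert the
assumed generative model — exactly at zero noise, without bias at stated
noise. It does *not* show robustness to what real samples add: bubble
stripping during handling, non-linear N$_2$O accumulation over the
incubation, anammox contributions to $^{29}$N$_2$, chimeric ORFs or
annotation error. Those are outside the generative model and outside the
package's claims.

Numerical and design details worth knowing:

* Generators are seed-deterministic (`scenario_config(seed = )`) and each
  emits a ground-truth sidecar; the ORF truth table records both the drawn
  Dirichlet shares and the realized shares after ORF assignment (taxa that
  drew no ORF carry no mass), and the exact-count mode (`exact = TRUE`)
  reproduces the realized shares to rounding error — the infinite-depth
  limit used in tests.
* Problem sizes in the shipped tests and analysis scripts (seven samples,
  40 ORFs per gene per sample, read depth $10^5$, 200 replicate
  incubations in the recovery study, $10^6$ pairs in the Monte-Carlo
  pairing oracle) were chosen so the whole suite runs in well under a
  minute while leaving Monte-Carlo standard errors far below the assertion
  tolerances.
* Concentrations are carried in consistent per-litre units with nmol/µmol
  only at I/O boundaries; the ×2 N-atom and ×44.013 g mol$^{-1}$
  conversions each live in a single function.
* Degenerate inputs have defined behavior: zero total NO$_3^-$ pool,
  $f_{15} = 0$, zero elapsed time and positive-slope standard curves are
  errors; all-zero read counts, zero equilibrium concentration with
  positive dissolved gas, and both-rates-zero end-product ratios are
  NA-with-warning.

## Known limitations

* The constant-k flux route is only as good as the supplied piston
  velocity; wind-based presets need a wind speed the user must provide.
* The soil upscaling inherits the reconstructed bulk density; treat the
  annual soil figure as conditional on that parameter.
* No anammox or DNRA partitioning: in soils where anammox contributes
  $^{29}$N$_2$, $R_{N_2}$ attributes it to denitrification.
* nosZ clade calls depend entirely on the user-supplied reference hit
  labels; the package only implements the vote.
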