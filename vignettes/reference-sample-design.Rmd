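---
title: "Designing and assessing mixture-based Cq reference samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and assessing mixture-based Cq reference samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cqmix)
```

# The measurement-assurance problem

A biomarker panel discovered in a research laboratory is only useful if a
second laboratory — often a regulated clinical one — can reproduce the
*differences* it reports between samples. `cqmix` implements a
reference-sample paradigm for RT-qPCR miRNA panels: build a *pair* of
samples from cultured cell lines whose relative miRNA abundances differ by
designed, predictable amounts, then use that pair to probe whether a
laboratory's measurement process (RNA isolation through quantification)
recovers the designed differences.

The package covers the full cycle:

1. **Profile** candidate component cell lines for the panel assays
   (quantification cycle, Cq, per analyte per line) under a two-laboratory
   crossover.
2. **Predict** the Cq profile of any mixture of those components in
   silico.
3. **Search** mixture-fraction pairs for a design whose per-analyte
   differences are usable.
4. **Measure** real mixtures (mixed RNA, or mixed intact cells) and
   compare against the design with dCq / ddCq statistics.
5. **Decompose** variance over the crossover factors, and **assess bias**
   between measurement scenarios with a Bayesian mixed-effects model.

# The additive abundance model

A Cq value is the PCR cycle at which fluorescence crosses threshold; each
cycle is a doubling, so a Cq of $Y$ corresponds to abundance proportional
to $2^{-Y}$, and lower Cq means more template. If component $c$ of a
mixture has Cq value $Y_c$ and mass (or count) fraction $\phi_c$ on the
unit simplex, and abundances combine additively and linearly, the mixture
has predicted Cq

$$\widehat{M} \;=\; -\log_2 \sum_c \phi_c\, 2^{-Y_c}.$$

`predict_mixture_cq()` evaluates this with the sum shifted by the smallest
component Cq (a log-sum-exp form). In double precision the naive form
would already be adequate down to the detection ceiling
($2^{-35}\approx 3\times10^{-11}$), but the shifted form costs nothing and
removes the concern entirely. Consequences of the model worth keeping in
mind:

* the prediction always lies between the smallest and largest contributing
  component Cq;
* lowering any active component's Cq strictly lowers the mixture Cq;
* components at the detection ceiling (default 35 cycles, single-molecule
  territory) contribute negligibly on the linear scale — they are flagged
  in outputs but deliberately not truncated or excluded.

The model fixes amplification efficiency at 2 per cycle and ignores
differences in miRNA fraction per total RNA between lines; both are known
simplifications.

# Designing the pair

Physically preparable mixtures use simple ratios (a 1:3:1 by-mass or
by-count mix is pipettable; a 0.217:0.583:0.2 one is not), so the design
space is a small grid: `enumerate_designs()` builds all distinct simplex
points with per-component weights from a ratio grid (default $\{1,3\}$)
and all unordered pairs of them — a pair and its label swap are the same
design, since swapping Mix1 and Mix2 only flips every dCq sign.

"A useful spread of differences" is made explicit in
`score_design_pair()`:

* **feasibility** — every target analyte's predicted
  $\mathrm{dCq} = \mathrm{Cq}_{\text{Mix1}} - \mathrm{Cq}_{\text{Mix2}}$
  has magnitude at most `max_abs_dcq` (default 1 cycle, i.e. two-fold up
  or down), and both signs occur, so the pair discriminates in both
  directions;
* **score** — the minimum pairwise distance between analytes in the
  Bland-Altman plane (mean Cq vs dCq, each axis scaled by 1 cycle by
  default). Maximizing the minimum separation keeps every analyte's
  designed difference distinguishable from every other's.

Strata (isolation replicates, labs) are averaged before scoring, mirroring
how a Bland-Altman plot of all strata is read by eye. `rank_designs()`
orders feasible candidates by score with deterministic tie-breaking
(smaller worst-case |dCq|, then lexicographic fractions).

```{r design-example}
cfg <- simulation_config()
profiles <- collapse_wells(simulate_profiling_phase(cfg, seed = 1))
profiles <- profiles[profiles$analyte != "MIR-16", ]
pair <- list(Mix1 = mixture_design("Mix1", colnames(cfg$cell_means),
                                   ratio = c(1, 3, 1)),
             Mix2 = mixture_design("Mix2", colnames(cfg$cell_means),
                                   ratio = c(3, 1, 1)))
score_design_pair(pair, profiles)
```

# dCq and ddCq

`delta_cq()` pairs Mix1 and Mix2 within (analyte, isolation replicate,
PCR lab, plate) and differences them; negative dCq means more starting
material in Mix1. Whether the two mixtures share a physical plate is a
layout fact the data cannot always reveal, so pairing is explicit
configuration: `"plate"` (default, co-plated) or `"isolation"` (average
plates first). `delta_delta_cq()` first subtracts a control analyte
(miR-16 here) measured on the same sample and plate, which cancels any
per-plate additive effect *exactly* — a property the test suite asserts at
machine precision. Summaries report group mean and sample SD (the $n-1$
denominator, matching the conventional reading of small-$n$ "± SD"
values).

# Variance decomposition

`factorial_anova()` computes the classical fixed-effects decomposition of
the total centered sum of squares over all main effects and interactions
of the supplied factors. The crossover design is balanced by construction,
so the closed-form nested-mean-differencing identity applies and the
decomposition is exact (conservation is asserted at $10^{-8}$ relative).
Unbalanced data (e.g. after dropping undetermined wells) fall back to
sequential Type-I sums of squares in the order given, with a logged
caveat — on balanced data the two coincide, so the distinction rarely
binds. Mean squares are used descriptively, as average contributions to
variability; no F-tests are reported, and `filter_report()` implements the
reporting convention of showing only terms with mean square at or above a
threshold (default 1 Cq²). The isolation replicate is treated as a fixed
factor here even though the Bayesian model treats isolation units as
random — the decomposition answers "where did the variability go in *this*
dataset", not an inferential question.

# Bayesian bias assessment

For one target analyte at a time, `fit_mixed_model()` models collapsed Cq
values as

$$y = \mu_{\text{cell}} + u_{\text{plate}} + v_{\text{isolation}} +
\varepsilon,$$

with a fixed mean per *cell* — each combination of source material
(in-silico, RNA mixture, cell mixture), isolation lab, PCR lab, and sample
— and zero-mean normal random effects. Two structural choices matter:

* **Isolation units are sample-preparation events** — keyed by
  (source, isolation lab, replicate, sample), because every cell line and
  every mixture is isolated (or mixed) separately. Keying by replicate
  alone would let preparation variation that differs between Mix1 and Mix2
  bypass the uncertainty of dCq functionals.
* **In-silico predictions carry no plate effect.** They are derived
  quantities, not physical plate measurements; giving them a pseudo-plate
  would confound that plate's effect with their cell means.

Sampling is Gibbs-within-Metropolis: fixed means and random effects have
conjugate normal full conditionals; the three SDs take random-walk
Metropolis steps on the log scale. Defaults: 4 chains, 5,000 iterations,
1,000 burn-in, diffuse N(25, 100²) priors on cell means (effectively flat
over the 0–40 Cq range). Split-$\hat R$ is computed for every parameter
and a warning is raised above 1.05; draws are deterministic given the
seed.

Three **model perturbations** probe sensitivity to prior choice:
variant 1 (reference) uses half-normal(5 Cq) priors on all SDs; variant 2
half-Cauchy(2.5); variant 3 removes the isolation random effect. These are
the package's own perturbations, chosen to bracket light-versus-heavy
tailed variance priors and the presence of the most influential random
term; `run_variants()` reports how far functional peaks move across them.

## Marginal-likelihood curves

Uncertainty about an average dCq (or a difference of average dCq values
between scenarios) is reported as a *marginal likelihood curve*: the
likelihood of the data as a function of that one quantity with all other
parameters integrated out, normalized to maximum 1. Because every
functional of interest is a linear combination of fixed cell means, and
those means carry effectively flat priors, the marginal likelihood is
proportional to the functional's posterior density (a Savage–Dickey-style
identity). `marginal_likelihood_curve()` therefore smooths the
functional's posterior draws with a Gaussian kernel (Silverman's rule) on
a grid spanning the mode ± 4 posterior SDs at 201 points.

The kernel estimate carries $O(\mathrm{bw}^2)$ smoothing bias: against an
exact conjugate normal posterior, the normalized curve is accurate to
about 5% sup-norm at 24,000 draws while the posterior mean and SD are
accurate to well under 1%. Peak locations — the quantity the curves are
read for — are unaffected to well within the grid resolution.

`compare_scenarios()` quantifies "do these scenarios agree" as pairwise
peak signs and an overlap coefficient (integral of the pointwise minimum
after normalizing each curve to unit area); overlap below a configurable
threshold (default 0.25) flags a separated pair, as a PCR-lab bias would
produce.

# What the synthetic generator does and does not emulate

`simulation_config()` encodes the study layout: six assays (five targets
plus the miR-16 control) across three lung-cancer cell lines (H226, H358,
H460); a profiling phase (3 isolation replicates × 2 isolation labs × 2
PCR labs × 3 wells, one plate per PCR-lab occasion); RNA mixtures (4
isolations, pairs measured on 3 plates at each of 2 PCR labs); and cell
mixtures (4 isolations, 3 plates, reference lab only).

Default true profiles were chosen so that the designed geometry matches
the study's qualitative structure: H358 highest in miR-21 and miR-210,
H226 highest in miR-126, H460 highest in miR-375, H358 ≈ H460 for
miR-486, miR-375/miR-486 near the 35-cycle ceiling in H226; mixture
abundance rank order 486 < 375 < 126 < 210 < 21; all designed |dCq| within
one cycle with both signs represented (miR-126 ≈ +0.55 at the reference
lab, miR-21 ≈ −0.8). Confounds are injected the way the crossover revealed
them: an isolation-lab shift for miR-21 (−0.4 cycles when isolated at
BRL, identical across lines so it cancels in dCq), and PCR-lab shifts for
miR-126/miR-486 that *vary across cell lines* (so they shift dCq and
create the analyte × line × PCR-lab interaction). Noise defaults, in
cycles: σ_iso = 0.15 per preparation event, σ_plate = 0.10 per physical
plate, σ_well = 0.15 per well, and a per-isolation component perturbation
(batch drift) of 0.10 in the mixture phases. No numeric variance
components are published for the study; these values were chosen once to
give realistic spreads (per-isolation dCq SDs of ~0.05–0.2) and are
plainly synthetic.

True mixture Cq values are always derived from (perturbed) component
profiles through `predict_mixture_cq()`, never drawn directly, so the
additive model holds exactly in the noise-free limit — which is also what
the generator's tests exploit.

What passing tests on these data do **not** show about real data: the
generator is Cq-level only (no amplification curves, no efficiency
variation), Gaussian in every random term, truncation-free at the
detection ceiling, and its additive-model truth means it cannot expose
violations of the linearity assumption itself (miRNA-fraction differences
between lines, efficiency ≠ 2). Those must be probed with real mixtures.

# Numerical and reproducibility choices

* Log-sum-exp evaluation of the mixture model; linear-scale additivity is
  asserted to $10^{-9}$ relative.
* Balanced-design detection is exact (equal counts in every full cell);
  anything else uses the sequential fallback.
* All simulation and MCMC randomness flows from explicit integer seeds;
  the two mixture phases offset the seed so phases are independent but
  jointly reproducible. Equal seeds give byte-identical outputs.
* Ties in design ranking are broken deterministically; grid/label order
  never depends on hash or locale ordering.
* Test-suite fits use shortened chains (2 × 1,500–2,500) — enough for the
  asserted properties; the convergence warning at those lengths is the
  diagnostic working as intended. Production defaults are 4 × 5,000.

# Known limitations

* The scenario numbering (pathways 1–7) follows the workflow layout and is
  configurable via `scenario_table()`; other numberings exist.
* The ddCq implementation requires the control analyte on the same sample
  and plate; sparse control coverage degrades to unit exclusion, never
  imputation.
* The Bayesian model is per-analyte; no information is shared across
  analytes, and variance components are not pooled.
* The marginal-likelihood construction relies on effectively flat priors
  for the fixed means; with strongly informative means priors the
  posterior-density identity would need the explicit prior correction.
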