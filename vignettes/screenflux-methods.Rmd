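---
title: "Scoring pooled transporter screens and estimating amino acid fluxes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring pooled transporter screens and estimating amino acid fluxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenflux)
```

# The problem

Pooled CRISPR interference/activation (CRISPRi/a) screens measure how
knocking down or overexpressing each gene in a library changes cell
proliferation, by sequencing single-guide RNA (sgRNA) barcodes before
and after growth. `screenflux` implements the gene-level scoring used
for solute-carrier (SLC) and ABC transporter screens — where the
readout of interest is fitness under nutrient limitation, in culture or
in xenografted tumours — together with the companion measurement:
absolute amino acid import, consumption and export rates estimated from
stable-isotope tracer time courses by GC–MS.

Both halves of the package come with synthetic-data generators that
carry known ground truth, so every stage of the pipeline is testable
without access to raw sequencing or mass-spectrometry data.

# Screen scoring model

## Per-sgRNA phenotypes

For a comparison of a treated (or endpoint) sample against a control
(or T0) sample, counts are depth-matched to the geometric mean of the
two sample totals, sgRNAs with fewer than `min_count` depth-matched
counts in *both* samples are excluded (100 by default; 25 for in vivo
screens, whose coverage per tumour is lower), and a pseudocount of
$\psi = 10$ damps ratio noise at low counts. The phenotype of sgRNA $i$
is

$$
\rho_i \;=\; \frac{1}{D}\left[\log_2\frac{c_{i,t}+\psi}{c_{i,c}+\psi}
  \;-\; \operatorname{median}_{\mathrm{NTC}}
  \log_2\frac{c_{j,t}+\psi}{c_{j,c}+\psi}\right],
$$

where $D$ is the number of population doublings of the comparison and
the median runs over non-targeting control (NTC) sgRNAs. Centring on
the NTC median makes the null phenotype exactly zero; dividing by $D$
expresses the phenotype per doubling, so a gene whose loss costs half a
doubling per doubling scores $\rho \approx -0.5$ regardless of how long
the screen ran. In vivo screens are scored without doubling
normalization ($D := 1$), because tumour doublings are not measured.

Depth-matching before the pseudocount keeps $\psi$ comparable across
samples of different depth; the pipeline is then invariant to uniform
rescaling of any sample's reads up to a small pseudocount effect
bounded by $\psi$ relative to the count filter.

## Gene scores

Each gene unit (10 sgRNAs) yields two statistics:

* the **phenotype score** (PS): the signed mean of the 7 phenotypes
  largest in absolute value — robust to a few inactive guides while
  keeping sign information;
* a two-sided **Mann–Whitney p-value** of all retained phenotypes
  against the NTC phenotypes.

The compact summary is the **screen score**
$\mathrm{SS} = \mathrm{PS}\cdot(-\log_{10}\max(p, p_{\mathrm{floor}}))$,
with $p_{\mathrm{floor}} = 10^{-16}$ guarding the logarithm. The
Mann–Whitney p-value uses the exact null distribution whenever both
groups have at most 25 untied values — which covers every group-size
regime in which agreement with exhaustive enumeration is asserted — and
the normal approximation with tie and continuity corrections otherwise
(the real 10-vs-730 comparisons).

Genes annotated with two transcription start sites carry 20 sgRNAs;
each TSS is scored as an independent 10-sgRNA unit and the gene reports
the unit with the larger $|\mathrm{SS}|$, since a gene is perturbable
if either of its promoters is. A unit must retain at least 5 sgRNAs
after count filtering to be scored at all; otherwise the gene is
reported unscored rather than scored from too few guides.

## The pseudogene null and hit calling

Technical noise is calibrated by **pseudogenes**: groups of 10 NTC
sgRNAs drawn at random from the 730-guide NTC pool, one pseudogene per
real gene, scored exactly like genes. Because 489 disjoint groups of 10
cannot be drawn from 730 guides, membership is sampled without
replacement within a pseudogene and with replacement across
pseudogenes.

One subtlety matters for calibration: a pseudogene's own sgRNAs would
otherwise sit inside the very NTC reference its Mann–Whitney test is
computed against, which biases its p-values conservative (on null
simulations, pseudogene screen scores come out roughly 12% narrower
than real-gene scores, enough for a two-sample Kolmogorov–Smirnov test
at $n = 489$ to notice). Real-gene sgRNAs are never part of the
reference, so pseudogenes are scored against the NTC reference
*excluding their own members*; with this leave-self-out reference the
real-gene and pseudogene null distributions are exchangeable.

Significance cut-offs are the extremes of the pseudogene screen scores.
With biological replicates, thresholds are taken from per-replicate
pseudogene scores before averaging while genes are called on the
replicate-averaged score — the averaged null is narrower by roughly
$\sqrt{n_{\mathrm{rep}}}$, so this is the stringent variant; pooling
thresholds across conditions implements the highest-scoring-control-in-
any-condition rule. An optional exclusion guards against
pan-resistance: significant hits whose per-replicate score in the
untreated control arm falls below $-0.12$ are excluded, unless they are
very strong resistant ($> 1.5$) or hypersensitive in the scored
condition. The hypersensitive bound is not quantified in the screen
literature; it defaults to $< -1.5$, mirroring the resistant override,
and is configurable.

## In vivo replicate QC

Tumour samples are noisy in a characteristic way: clonal expansion
skews individual sgRNA counts. Per sample the noise metric is the
number of NTC sgRNAs whose count is not within 1 log2 of the sample's
median NTC count; the two noisiest of six tumours are excluded, and
survivors are paired by noise-metric rank (quietest with
second-quietest, and so on — the pairing rule is not dictated by the
procedure, only the averaging), their counts averaged after matching
totals. For comparison across environments, screen scores are
normalized to the most depleted gene (scaled so its score is exactly
$-1$).

# Tracer kinetics model

## Steady-state label exchange

Import assays switch cells into medium in which the amino acids are
uniformly fully heavy-labelled. At steady state the intracellular pool
$P$ is constant, so the heavy-labelled portion follows first-order
exchange

$$
H(t) = P\,(1 - e^{-kt}), \qquad k = J_{\mathrm{in}}/P,
$$

and the initial slope of $H$ equals the import flux $J_{\mathrm{in}}$.
The estimator is an ordinary least-squares line over the timepoints in
a per-amino-acid window (0–100 s for Asn, Asp, Gln, Glu, Pro; 0–40 s
for Arg, Gly, His, Ile, Lys, Ser, Thr, Val; 0–20 s for Leu, Tyr; 0–10 s
for Phe — shorter windows for faster-exchanging pools), reported as
pmol min⁻¹ per 10⁶ cells with the slope's standard error. The pool
turnover constant is $k_{\mathrm{turn}} = J_{\mathrm{in}}/P$ in min⁻¹,
computed as import rate over the intracellular level (the mean total
pool across timepoints).

## Correction chain

Raw isotopologue ion counts pass through, in this order:

1. **Natural-abundance correction.** The forward model is a convolution
   matrix $A$ built from the fragment's molecular formula: column $j$
   convolves the natural isotope distributions of all atoms except the
   $j$ tracer-labelled carbons and shifts by $j$; the underlying
   labelling distribution solves $\mathrm{obs} = Ax$ by non-negative
   least squares (a direct solve is used when it is already
   non-negative). The formula is user-supplied, so derivatization atoms
   (e.g. Si from TBDMS silylation) can be included or not as the
   measured fragment requires.
2. **Internal standard.** Each timepoint is divided by the ratio of its
   norvaline signal to the mean norvaline signal.
3. **Steady-state TIC.** Import assays divide by the ratio of the total
   ion count (excluding norvaline) to its mean; consumption assays
   divide by the ratio to a fitted linear TIC trend, since medium
   withdrawal makes the raw TIC drift systematically rather than
   randomly. Consumption assays additionally apply the **volume
   correction**: signals are concentration-proportional, so each
   timepoint is rescaled to the whole-well equivalent (remaining-volume
   fraction) plus the running tally of analyte already withdrawn — on
   constant-concentration medium the corrected trace is exactly flat,
   and in general its slope equals minus the consumption rate.
4. **Absolute quantification.** A per-amino-acid standard curve
   (unweighted OLS of ion counts on pmol, free intercept, at least 3
   dilution points) converts the total ion count to pmol, scaled by the
   standards-to-sample norvaline ratio; the total is distributed over
   isotopologue channels in proportion to their signals. Negative
   totals below the intercept clip to zero with a warning.

The internal-standard and ratio-to-mean TIC steps are both row-wise
multiplicative, but they do **not** commute when the norvaline signal
drifts — each changes the factors the other computes. The order above
is therefore part of the method, fixed and tested (the orders coincide
exactly when norvaline is constant).

## Which channels count as "heavy"

Because labelling is all-or-none per molecule, the corrected labelling
distribution concentrates at the fully-labelled channel $x_n$;
intermediate channels are zero in expectation and, in data, carry only
correction noise whose scale is set by the (large) unlabelled pool
rather than by the (small, early) labelled signal. The import and
export estimators therefore read $x_n$ by default; summing
$x_1 \dots x_n$ remains available (`heavy = "all_labelled"`) for
partially-labelled designs. On the package's own recovery benchmark the
channel sum roughly doubles the median rate error.

# What the generators emulate

* **Screens** (`simulate_screen`): lognormal initial library
  representation (sigma 0.5, a typical representation spread for a
  well-cloned pool), exponential growth over $D$ doublings in which
  sgRNA $i$ targeting gene $g$ expands as
  $2^{D(1 + \mathrm{eff}_i e_g)}$, and multinomial read sampling at
  fixed depth (500 reads per sgRNA by default; a Dirichlet
  overdispersion knob is available). NTC effects are exactly zero. The
  per-doubling growth parameterization makes the analytic expectation
  of $\rho$ equal $e_g$ after doubling normalization.
* **Tracer assays** (`simulate_tracer`): the first-order exchange model
  above, convolved with natural abundance, scaled to ion counts, with
  multiplicative lognormal noise (5% CV in the recovery suites) and a
  norvaline channel; consumption assays integrate medium depletion
  through the withdrawal schedule (15 µl per timepoint from 300 µl,
  against a medium pool of 10⁵ pmol — a few hundred micromolar, the
  scale of growth media); export assays grow a labelled amount
  $J_{\mathrm{out}}t$ over an unlabelled background.
* **Competition assays** (`simulate_competition`): qPCR Ct values from
  a 1:1 starting mix under perfect per-cycle doubling, such that the
  noiseless records are exactly inverted by `competition_phenotype`
  ($-\Delta\Delta C_t / D$, negative = depleted, matching screen-score
  signs; primer efficiency is assumed exactly 2 per cycle).

What they do *not* emulate: PCR amplification bias, sgRNA off-target
effects, guide-to-guide efficacy structure beyond a supplied
multiplier, tumour spatial clonality, chromatographic peak integration,
or instrument drift beyond multiplicative noise. Passing recovery tests
therefore demonstrates correctness of the estimators under the stated
noise models, not robustness to every artefact of real data.

# Problem sizes and numerical choices

The test and acceptance suites run the full 489-gene, 5,990-guide
library with 2 replicates at depth 500 reads per sgRNA over 10
simulation seeds for both the spiked-recovery and null-calibration
checks; tracer recovery uses 100 random series over
$J_{\mathrm{in}} \in [1, 500]$, $P \in [50, 5000]$ with the import
sampling schedule 0–250 s. These sizes keep each suite to a couple of
minutes while leaving the binomial/KS checks well-powered.

Other numerical choices: Mann–Whitney switches from the exact
distribution to the corrected normal approximation beyond group size 25
or in the presence of ties; p-values are floored at $10^{-16}$; the
abundance-correction matrix is rejected if its reciprocal condition
number falls below $10^{-12}$; rate regressions require at least 3
points in the window; effective cell number defaults to 0.64 × 10⁶
(0.8 × 10⁶ monolayer minus 20% wash loss) and is configurable
everywhere.

# Known limitations

* The window schedule is static per amino acid; when simulated kinetics
  are much faster than the window assumes ($k t_{\max} \gtrsim 1$) the
  initial-slope estimate is biased low, which is the dominant error
  mode in the recovery benchmark (noiseless median bias ≈ 4%).
* In vivo scoring inherits whatever noise survives the NTC-dispersion
  QC; the pairing rule for surviving tumours is a package choice.
* The untreated-arm exclusion's hypersensitive override is a package
  default, not a published constant.
* Competition phenotypes assume perfect primer efficiency; an
  efficiency-corrected mode would need measured efficiencies.
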