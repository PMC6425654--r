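---
title: "Dosage calling for autotetraploid SNP arrays: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosage calling for autotetraploid SNP arrays: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetradose)
```

## The problem

An autotetraploid individual carries four copies of each chromosome, so a
biallelic SNP can be present in five allele dosages: 0 (nulliplex) through 4
(quadruplex).  Two-channel SNP arrays report a fluorescence intensity per
allele, `s_a` and `s_b`; the continuous signal ratio `s_b / (s_a + s_b)`
must be converted into one of the five discrete dosage classes.  `tetradose`
does this by fitting, per marker, a five-component normal mixture to the
arcsine-square-root transformed ratio

$$y = \arcsin\sqrt{\frac{s_b}{s_a+s_b}} \in [0, \pi/2],$$

a variance-stabilizing transform under which the five dosage clusters have
approximately equal spread.  The mixture density for sample $i$ is

$$f(y_i) = \sum_{j=1}^{5} \pi_j\, \phi(y_i;\, \mu_j, \sigma^2),$$

with strictly increasing means $\mu_1 < \dots < \mu_5$, a common variance
$\sigma^2$, and mixing proportions $\pi_j$.  Dosage $j-1$ is called for a
sample when its posterior class probability
$p_{ij} = \pi_j \phi(y_i)/f(y_i)$ reaches the call threshold.

## Multi-population structure

Real genotyping runs mix sample types: a full-sib (F1) family, its two
parents in replicate, and unstructured panels.  The component means and
variance describe the assay chemistry and are therefore shared across all
subpopulations, while the mixing proportions describe genetics and are
population-specific.  Four constraint regimes are available per population:

* **p_free** — only $\sum_j \pi_j = 1$; the M-step takes the mean posterior.
* **p_HW** — tetraploid Hardy-Weinberg equilibrium: $\pi$ is Binomial(4, p)
  in the allele frequency $p$, estimated in the M-step as the posterior mean
  dosage divided by 4 (this is the exact maximizer of the expected
  complete-data log-likelihood within the HW family).
* **p_fixed** — a parent population with a known dosage $d$.  Rather than a
  literal 0/1 vector we use a spiked vector with leak probability
  $\varepsilon = 0.02$ per other class ($\pi_d = 1 - 4\varepsilon$):
  replicated parent samples occasionally contain outliers or sample
  mix-ups, and a degenerate vector would zero their likelihood.
* **p_F1** — the expected tetrasomic segregation of the linked parents'
  current modal dosages (see below).

## Tetrasomic segregation

Under random bivalent pairing without double reduction, a gamete receives 2
of the parent's 4 homologs, so gamete dosage is hypergeometric:

$$P(g \mid d) = \binom{d}{g}\binom{4-d}{2-g}\Big/\binom{4}{2},
  \qquad g \in \{0,1,2\}.$$

The F1 offspring distribution is the convolution of the two parental gamete
distributions; for example duplex x duplex yields 1:8:18:8:1 and duplex x
quadruplex yields 0:0:1:4:1.  `f1_segregation()` computes this from the
formula; the exhaustive 25-cell reference table serves as its test oracle.
Double reduction is deliberately not modelled (it is rare under
predominantly bivalent pairing), and no parameter for it is exposed.

## The EM algorithm and its numerical choices

The engine alternates an E-step (population-aware posteriors) with M-steps
for $(\mu, \sigma^2)$ and then for each population's $\pi$, until the
observed-data log-likelihood changes by less than `em_tol` (default 1e-6,
at most 500 iterations).  Numerical choices, all config-exposed:

* **Variance floor** $\sigma^2 \ge 10^{-6}$ prevents collapse onto a single
  point mass.
* **Starting values** without priors: hard assignment by cutting `y` at the
  ratio midpoints $\arcsin\sqrt{(j+0.5)/4}$, class means as initial $\mu$
  (the theoretical mean for empty classes), pooled within-class variance,
  uniform $\pi$ (HW panels start at the moment estimate of $p$).
* **Label switching**: if a free-means M-step breaks monotonicity of $\mu$,
  components are re-sorted and the posteriors and proportions relabelled.
* **Constrained means.**  The "background" variants model the two channel
  responses as $f_B(j) = c_b + j(1+kj)$ and $f_A(j) = c_a + (4-j)(1+k(4-j))$
  with $\mu_j = \arcsin\sqrt{f_B/(f_A+f_B)}$, covering equal/unequal
  backgrounds ($c_a = c_b$ or not) and linear/quadratic dose response
  ($k = 0$ or $k > 0$).  These are fitted inside the M-step by bounded
  weighted least squares (`optim` L-BFGS-B, multi-start from three fixed
  points plus the current value, which guarantees the step never worsens
  the fit).  The implied means are strictly increasing for any nonnegative
  parameters, so the order constraint is automatic.
* **The p_F1 likelihood guard.**  Plugging the parental modal dosages into
  the segregation table is the natural update but is not an ascent step: a
  transient flip of a parental mode can crash the likelihood by hundreds of
  units.  We therefore accept the plug-in row only when it does not lower
  the F1 population's observed log-likelihood under the current means and
  variance; otherwise the best-fitting candidate among the 25 segregation
  rows and the current vector is used.  With well-behaved data the guard is
  inactive and the behaviour is exactly the plug-in; the guard only
  enforces the EM monotonicity property that the rest of the algorithm
  already has.  Modal-dosage ties are broken toward the dosage nearest the
  population's posterior-mean dosage, then toward the lower dosage.

## Model grid, BIC, and parental priors

Per marker, the grid is the product of the five mean variants with up to
three proportion configurations — all-free; structured (HW panels, F1
segregation, free parents); and, when dosage priors exist, structured with
`p_fixed` parents.  Keeping the all-free and prior-free configurations in
the grid means a wrong prior (e.g. derived from RNA-Seq with allelic
expression bias) can be outvoted.  Selection is by BIC,
$-2\ell + k\ln n$, with $k$ counted as: 1 for $\sigma^2$; 5 (free), 2
(linear-equal), 3 (linear-unequal, quadratic-equal) or 4
(quadratic-unequal) for the means; and per population 4 (`p_free`), 1
(`p_HW`), 0 (`p_fixed`, `p_F1`).  Ties prefer fewer parameters, then the
fixed grid order.  The whole pipeline is deterministic: no random numbers
are consumed during fitting.

When both parents of a family have distinct priors and observed replicates,
their mean `y` values pin two component means and the other three come from
the straight line through the two (dosage, mean) points, clipped into
$(0, \pi/2)$; equal priors pin a single mean on top of the default seeding.

**Re-evaluation of sparse extremes.**  A fitted extreme class (dosage 0
or 4) holding under 2.5% of all samples next to a neighbour holding over
15% is genetically implausible (in an HW panel a rare homozygote implies a
rare allele and hence a rare adjacent class; in an F1 only the duplex x
duplex cross approaches it).  The model is refitted with that component
forced to zero everywhere and the refit kept only if BIC improves.  We
remove the component globally (not per population): the means are shared,
so a spurious extreme component is an artefact of the shared geometry.  For
HW populations the forced zero is imposed by renormalizing after the HW
M-step, which technically leaves the HW family; we accept this in the
4-component fallback.  Parameter counts are left unchanged in the refit's
BIC, a conservative choice (the refit is penalized as if it were full).

## Calling and marker filters

Samples are called at posterior `call_threshold` (default 0.75); parents
are called from their posteriors like any other sample, never from their
priors.  Markers are then filtered: more than 25% missing calls rejects the
marker (`rejected_too_many_na`); more than 90% of called samples in a
single dosage class rejects it (`rejected_single_category`, such markers
are uninformative and often monomorphic artefacts); a marker with no
converged fit is `no_model`.  The four statuses partition every run.

## Parent-offspring QC

For each called marker with an F1 family, the called offspring counts are
compared by Pearson chi-squared against the expected proportions of all 15
unordered parental dosage pairs; a pair expecting zero in an observed class
is impossible and scores infinity.  The minimum-statistic pair is compared
with the parents' modal called dosages; agreement makes the marker
"matching".  We use hard counts of called offspring (not posterior-weighted
proportions — the alternative is noted but not implemented) and no p-value
cutoff, because the procedure asks which pattern fits *best*, not whether
it fits absolutely.  Some patterns are near-indistinguishable (1:8:18:8:1
vs 0:1:2:1:0); when the two best statistics differ by less than 10% the
report is flagged ambiguous.  A marker whose parents lack called
replicates is "not assessable" and counts as not matching in run totals,
kept distinguishable in the per-marker report.

## The synthetic-data generator

`make_test_layout()` emulates the archetypal experiment: one tetraploid F1
family (default 200 offspring; 975 at `full_scale`), both parents
replicated 12 and 13 times, and an HW panel (60; 222 at full scale).
Defaults state the assumed world: ideal component means
$\arcsin\sqrt{j/4}$ (zero background, linear response), noise
$\sigma = 0.04$ on the transformed scale — the regime in which arrays are
worth calling, clusters separated by 5-6 $\sigma$ — and 2% missing signal
pairs.  Dosages are drawn from the population model (HW proportions,
segregation ratios, fixed parental dosage); noise is added on the
transformed scale where the model assumes constant variance, and signals
are reconstructed with unit total intensity.  Per-marker seeds derive
deterministically from one master seed.

What the generator does **not** emulate: background shifts and curvature
unless requested (set `mean_param`), class-dependent variance, intensity-
dependent noise, batch and plate effects, and null alleles.  A green test
on synthetic data therefore establishes algorithmic correctness under the
model's own assumptions, not robustness to array artefacts.

## Known limitations

* Autotetraploids only; no disomic/allopolyploid segregation, no higher
  ploidies, no double reduction.
* Continuous signal models only; no sequencing read-count likelihoods.
* One shared $\sigma^2$ per fitted model; heteroscedastic components are
  not modelled.
* The published large-array benchmark (1000 SNPs, 1502 samples) cannot be
  redistributed with the package; the acceptance suite covers the
  algorithmic criteria and a reduced-scale synthetic analogue of the full
  pipeline instead.

## A worked example

```{r example, eval = FALSE}
spec <- make_test_layout(n_markers = 3, seed = 42)
ds <- simulate_dataset(spec)
res <- fit_markers(ds$signals, ds$structure, ds$priors)
reports <- lapply(res, classify_marker, structure = ds$structure)
summarize_run(res, reports)
```
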