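---
title: "Attentional and cholinergic modulation of spike trains: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attentional and cholinergic modulation of spike trains: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cholattn)
```

## The problem this package addresses

Prefrontal neurons recorded during covert spatial attention tasks carry two
kinds of attentional signal: a change in mean firing rate when the animal
attends the stimulus in the neuron's receptive field (RF), and a reduction in
trial-to-trial rate variability. Local pharmacology (iontophoretic
acetylcholine, or blockade of muscarinic/nicotinic receptors) modulates both.
Quantifying these effects requires a chain of estimators — ideal-observer
AUROC, factorial ANOVA screening, negative-binomial gain-variance fits,
normalized modulation indices, Gaussian-mixture cell-type clustering with a
calibrated dip test, and signal-detection behavioral summaries — each of
which is easy to get subtly wrong. `cholattn` implements that chain as
tested, reusable functions, together with a synthetic-data module that
reproduces the task structure and spiking statistics with known ground
truth, so every stage can be validated end to end without recorded data.

## The generative model

A simulated cell is a gamma-renewal process with a per-trial multiplicative
excitability gain. On each trial:

1. A gain $G$ is drawn from a gamma distribution with mean 1 and variance
   $\sigma^2_G$, scaled per condition: attend-RF trials multiply
   $\sigma^2_G$ by `gain_var_attend_scale` (default 0.7 in the panel,
   emulating attentional stabilization), drug-on trials by
   `gain_var_drug_scale`.
2. The firing rate is $\mu = G \cdot r_\text{base} \cdot
   g_\text{drug}^{[\text{drug on}]}$, with the attentional gain
   $g_\text{att}$ switching on at cue onset on attend-RF trials. Under drug
   the attentional gain excess is rescaled:
   $g_\text{att}^{(drug)} = 1 + s\,(g_\text{att} - 1)$.
3. Spike times are a gamma renewal process with shape $\kappa$
   (`isi_shape`), generated in operational time and warped through the
   piecewise-constant integrated rate. This makes regularity and rate
   modulation independently controllable: the expected local variation is
   $\mathrm{E}[Lv] = 3/(2\kappa + 1)$ regardless of rate, and for
   $\kappa = 1$ the spike count $N$ in a window with expectation $\lambda$
   is a gamma-Poisson mixture with
   $\operatorname{Var}(N) = \lambda + \sigma^2_G \lambda^2$ — exactly the
   negative-binomial structure the gain-variance fit assumes.

The trial schedule fixes stimulus onset at 0 ms, draws the cue onset
uniformly in 300–1400 ms, and the first dimming 1500–2100 ms after the cue,
so the three canonical analysis windows (100–400 ms after stimulus onset,
100–400 ms after cue onset, −500–0 ms before the first dimming) exist in
every trial. Three attention conditions (RF and two away locations) crossed
with two motion directions give six stimulus conditions per drug state. The
generator applies the attentional gain as a step at cue onset; the true
within-trial time course in cortex is gradual, but the step is sufficient
for every window-based analysis performed here.

### The archetype panel

`archetype_panel()` defines four broad (B1–B4) and three narrow (N1–N3)
spiking archetypes. Waveform widths straddle the 250 µs narrow/broad
boundary; rates span 4–40 spikes/s; regularity spans $\kappa$ = 0.5–4
(Lv ≈ 1.5 down to ≈ 0.33); attentional gains span 1.10–1.80; gain variances
span 0.05–0.60. The combinations are deliberately scrambled across
archetypes so that no single feature axis carries all the between-class
variance — a property real cell classes share, and the reason the
explained-variance screening retains several features rather than one. N3
emulates the putative fast-spiking interneuron class: very narrow spikes,
high regular rates, low gain variance. The drug profiles set multiplicative
rate gains above 1 with gain-variance scalings below 1 for ACh (excitation,
variability reduction), and the reverse for muscarinic (Scop) and nicotinic
(Mec) blockade; the Mec profile leaves the attentional gain of broad cells
untouched, mirroring a nicotinic contribution to attentional modulation
confined to narrow spiking cells.

What the generator does *not* emulate: drifting excitability across a
session (gains are i.i.d. across trials), bursting and refractory structure
beyond the renewal shape, spike-sorting contamination, correlated
variability between simultaneously recorded cells, and eye-movement
artifacts. Passing tests therefore validate the estimators under the model
class they assume, not robustness to these departures.

## Analysis stages and their parameters

**Waveform width.** Trough-to-peak time is measured on a 10× cubic-spline
interpolation of the mean waveform (sub-sample stability; the raw 25 µs
sampling grid would quantize the 250 µs boundary). Cells with
P2T ≤ 250 µs are narrow, others broad; waveforms without a trough-then-peak
shape are flagged invalid.

**ISI statistics.** ISIs are formed within trials only. CV uses the pooled
ISIs; CV2 and Lv average over adjacent within-trial pairs. For clustering,
regularity features are pooled over all *no-drug* trials — features should
describe the cell's intrinsic physiology, not the manipulation. The Fano
factor feature uses predimming counts in the attend-RF no-drug condition
(averaged over the two directions), and the firing-rate feature the mean
predimming rate over no-drug trials; the source epochs are configurable
because no single convention is canonical.

**ANOVA screen.** A fixed-effects attention × direction × drug factorial
on per-trial predimming rates, Type-II sums of squares for unbalanced
designs (each effect tested against the model with all terms not involving
it), α = 0.05 two-sided. A cell is attention (drug) modulated when the main
effect or any interaction involving that factor is significant. Type-II was
chosen over Type-I/III because it is invariant to factor order and respects
marginality; the choice is testable against a brute-force model-comparison
oracle.

**AUROC and Cohen's d.** The pair-counting estimator
$(\#\{x > y\} + \tfrac12\#\{x = y\})/(n_1 n_2)$, equal to the
Wilcoxon–Mann–Whitney $U/(n_1 n_2)$, computed on predimming rates for
attend-RF versus attend-away, separately per drug state. Both away
locations and both directions are pooled into the away sample by default
(maximizing trials; configurable). A folded variant
$\max(A, 1 - A)$ is reported alongside, never instead of, the raw value.

**Gain variance.** Counts in the predimming window are fitted per stimulus
condition with the negative binomial parameterized by mean $\lambda$ and
gain variance $\sigma^2_G = 1/\text{size}$:
$\operatorname{Var} = \lambda + \sigma^2_G\lambda^2$. $\hat\lambda$ is the
sample mean (its exact MLE in this parameterization), and $\sigma^2_G$
maximizes the one-dimensional profile likelihood on $[0, \text{upper}]$
with a method-of-moments start — a deliberate avoidance of 2-D optimizer
fragility. Under-dispersed counts land on the boundary
$\hat\sigma^2_G = 0$ (the Poisson submodel) and are reported as converged.
Fits require at least 5 trials (no floor is canonical; 5 keeps the
likelihood informative while excluding degenerate conditions). The two
attend-RF condition fits and the four attend-away fits are averaged
arithmetically, separately per drug state.

**Modulation indices.** All indices are of the form $(a - b)/(a + b)$:
drug MI on condition-mean rates (no drug minus drug, so excitation is
negative), drug gain MI on gain variances, and attention gain MI oriented
away-minus-RF so that attentional stabilization is positive (the
orientation is a package convention; the headline direction is what
matters). The per-cell drug MI averages the per-condition MIs across the
six stimulus conditions (mean-of-MIs); the MI-of-means order is also
implemented and selectable, since either reading of "averaged across
attention conditions" is defensible.

**Clustering.** Candidate features {P2T, CV, CV2, Lv, FR, FF, AUROC} are
z-scored; cells with any missing feature are excluded and listed.
`screen_parameters()` selects features greedily by marginal gain in the
fraction of total variance explained by the selected subset's span (PCA
importance breaks ties) until ≥ 90% is reached — marginal-gain greedy
rather than rank-order greedy so that of two nearly collinear features only
one survives. Diagonal-covariance Gaussian mixtures are then fitted for
k = 2..12, each taking the best of the deterministic hierarchical
initialization and 100 random-start EM runs; restarts whose EM leaves a
component with fewer expected members than features + 1 are discarded,
because such splinters collapse a variance and inflate the likelihood
without meaning. AIC = 2p − 2ℓ and BIC = p ln n − 2ℓ use
p = 2kd + (k − 1). When AIC and BIC disagree, the solution with less
narrow/broad width mixing (summed per-cluster minority fraction) wins;
when the mixing scores tie, the more parsimonious k wins. AIC alone is
known to be liberal for mixture order selection — on planted-archetype data
its argmin often exceeds the planted count by fitting sampling clumps —
and the mixing-then-parsimony rule is what makes the selection reproduce
planted structure reliably.

**Dip test.** Hartigan's dip — the sup-norm distance from the ECDF to the
nearest unimodal distribution function — is implemented from a
band-feasibility characterization: a unimodal cdf within $t$ of the ECDF
exists iff, for some support point (the mode, possibly carrying an atom), a
convex nondecreasing function fits the band up to that point, a concave one
from it onward, and the two join monotonically; a mode interior to an empty
gap is dominated by one of the adjacent point-mode solutions. Each
condition is linear in $t$, giving an exact $O(\text{splits})$ scan with
lazy evaluation of the junction condition. The implementation is validated
in the test suite against an independent minimax linear program. The dip is
at least $1/(2n)$ and approaches $1/4$ for balanced two-point samples; for
well-separated but *spread* modes it is governed by each mode's internal
shape, so significance requires a few dozen points per mode. Calibration is
by bootstrap from the uniform distribution (the standard reference null),
10,000 draws by default (2,000 in the pipeline default for speed; the
smallest attainable p is $1/(n_\text{boot}+1)$), FDR-adjusted across
clusters with Benjamini–Hochberg.

**Behavior.** Hit rate is reported target dimmings over target dimmings
shown; correct rejection rate is unreported distractor dimmings over
distractor dimmings shown; d′ = z(hit) − z(FA) with rates of exactly 0 or 1
clipped by 1/(2N) (no correction is canonical; 1/(2N) is the common
convention and is flagged with a warning). Reaction times of correct
responses are divided by their session mean, making the session mean
exactly 1, and analyzed with a drug × attention (RF vs pooled away)
fixed-effects ANOVA plus per-condition Welch t tests.

## Reproducibility

Every stochastic stage takes a seed; `run_pipeline()` derives one seed per
stage from the master seed with a deterministic string hash, so a single
integer reproduces a whole run bit-for-bit, and the run manifest records a
hash of the configuration. The canonical on-disk schema is plain text:
`trials.csv`, `spikes.csv` (cell, trial, spike time in ms relative to
stimulus onset), `waveforms.csv`, and a JSON ground-truth sidecar. This
package is a library rather than a shell tool: the pipeline entry point is
`run_pipeline()` with a `run_config()` object, and `scripts/acceptance.R`
is a thin script over exported functions.

## Problem sizes

The test suite and acceptance script run at sizes chosen to make each
property measurable with comfortable margins: gain-variance recovery uses
200 simulated cells × 200 trials per grid point
($\sigma^2_G \in \{0, 0.1, 0.25, 0.5\}$, $\lambda \in \{5, 20\}$); ISI
analytics use 10,000 ISIs at $\kappa \in \{0.5, 1, 2, 4\}$; cluster
recovery plants 30 cells per archetype with 15 trials per condition; the
null ANOVA calibration uses 1,000 cells; behavioral rates use sessions of
8,400 trials. Population-level comparisons are fixed-effects factorials
throughout; a mixed-model treatment (cells as random effects) would need
assumptions about the random-effects structure that the per-cell schema
does not encode, and the fixed-effects version is the testable core.

## Known limitations

* The generator's per-trial gains are i.i.d.; slow excitability drift
  would inflate measured CV and Fano factors relative to the fitted model.
* The negative-binomial fit assumes Poisson conditional counts; for very
  regular cells ($\kappa \gg 1$) counts are under-dispersed at fixed gain
  and $\hat\sigma^2_G$ is biased downward — visible in the N3 archetype,
  harmless for direction-of-effect conclusions, but a caveat for absolute
  gain-variance values.
* AIC's argmin alone is not a reliable cluster-count estimator on mixture
  data; conclusions should rest on the full selection rule.
* The dip test has limited power below a few dozen points per putative
  mode; untestable clusters (< 10 cells) are flagged rather than tested.
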