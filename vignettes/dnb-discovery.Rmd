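---
title: "Finding dynamical network biomarkers by multi-objective search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding dynamical network biomarkers by multi-objective search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moodnb)
```

## The model

Complex diseases often progress through three coarse stages: a normal
state, a *pre-disease* state at the limit of the normal regime, and a
disease state that is hard to reverse once a tipping point has been
crossed. Near such a critical transition, bifurcation theory predicts that
a small group of molecules — the dynamical network biomarker (DNB), also
called the leading network — starts to behave distinctively: its members
fluctuate more strongly, become tightly correlated with each other, and
decouple from the rest of the system. `moodnb` looks for such groups in
time-course case/control expression data.

For a candidate gene group \(D\) at time-point \(t\), three moment
statistics are computed from the case samples:

* \(\mathrm{SD}_{in}(t)\): the mean, over genes in \(D\), of the sample
  standard deviation across replicates;
* \(\mathrm{PCC}_{in}(t)\): the mean absolute Pearson correlation over
  distinct pairs inside \(D\);
* \(\mathrm{PCC}_{out}(t)\): the mean absolute Pearson correlation over
  pairs spanning \(D\) and its complement.

They are combined multiplicatively into the composite early-warning index

\[
I_t(D) \;=\; \frac{\mathrm{SD}_{in}(t)\,\mathrm{PCC}_{in}(t)}
                  {\max(\mathrm{PCC}_{out}(t), \varepsilon)},
\qquad \varepsilon = 10^{-8},
\]

which rises sharply when the group simultaneously fluctuates, synchronizes
internally, and decouples from the background. The \(\varepsilon\) floor
guards against division blow-up for fully decoupled groups; absolute
values are used in both correlation averages because the criteria concern
correlation *magnitude*, not sign.

## The bi-objective formulation

A useful early-warning group must show a strong signal *now* and no signal
*one sampling time earlier* — otherwise it describes an established
disease module rather than the onset of the transition. Because an
unintervened disease course does not revisit the pre-disease stage, the
look-back covers only the immediately preceding sampling time. Both goals
are cast as minimization with the ideal point at the origin:

\[
f_1(D) = \frac{1}{1 + I_t(D)}, \qquad f_2(D) = I_{t-1}(D).
\]

The reciprocal transform for \(f_1\) was chosen over the raw \(-I_t\)
because it makes the ideal solution a finite point \((0, 0)\), which the
decision rule (Euclidean distance to the ideal) and the significance test
both rely on. The transform is monotone, so it does not change the Pareto
order of candidate groups.

Subsets are encoded as binary strings of length \(n\) and searched with a
canonical elitist NSGA-II (binary tournaments on rank and crowding
distance, uniform crossover, per-bit mutation, \(\mu+\lambda\)
environmental selection). Defaults follow the reference study settings:
population 500, crossover rate 0.8, per-bit mutation rate 0.01, 100
generations, and a returned front capped at 20% of the population.
Implementation choices the canonical algorithm leaves open:

* **Initialization** sets each bit with probability `min_size * 5 / n`.
  Dense random strings over hundreds of genes average away the composite
  index and give the first generations no gradient; a sparse start
  produces interpretable module-sized candidates immediately.
* **Feasibility repair**: variation can produce subsets below `min_size`
  (default 2 — a correlation needs a pair) or covering every gene (no
  complement for \(\mathrm{PCC}_{out}\)). Undersized subsets gain random
  bits; a full subset loses one.
* **Duplicate bit-strings** are collapsed in the returned front, and the
  front is then truncated by crowding distance; solutions are reported as
  distinct gene sets.
* All tie-breaks are driven by a single root seed, and every per-time run
  derives its own seed from it, so results are bit-reproducible.

## Significance of a Pareto set and the selection rules

For each solution of a front, a random gene set of the same size is drawn
and evaluated with the same objectives. The distances to the ideal point
of the observed and null collections are compared with a one-sided
Wilcoxon–Mann–Whitney test (observed stochastically smaller). The
Anderson–Darling normality statistic of both samples is attached purely as
a diagnostic: distance distributions are generally non-normal, so the
procedure always uses the rank test rather than branching to a parametric
one. The exact rank-sum distribution is used when both samples have at
most 8 observations and no ties; otherwise the normal approximation with
tie and continuity corrections.

The pre-disease time is the scanned time with the smallest
Wilcoxon–Mann–Whitney p-value (ties resolved toward the earliest time);
the biomarker is the Pareto solution closest to the ideal point (ties:
smaller set, then lexicographically smallest bit-string). When several
times have near-minimal p-values the per-time table and the trajectory
data in the report deserve a closer look before trusting the argmin —
`tidy()` on a scan set and `autoplot()` exist for exactly that.

## Preprocessing

The chain mirrors standard practice for time-course case/control arrays:

1. **Probe aggregation**: probes mapping to the same gene are averaged;
   probes with no mapping are dropped.
2. **Differential expression**: per time-point, a moderated Welch test
   \(t = (\bar{x}_{case} - \bar{x}_{ctrl})/(s + s_0)\). The offset
   \(s_0\) (default 0, i.e. the plain Welch test) damps statistics driven
   by tiny variances. P-values are Benjamini–Hochberg adjusted *within*
   each time-point; genes need \(q \le 0.01\) and a fold change
   \(\ge 2\) or \(\le 0.5\) at one time-point or more to be kept. BH was
   preferred over Storey's estimator because it is deterministic and has
   no tuning parameter; adjusting per time-point (rather than pooling all
   gene-by-time tests) follows the per-time testing design, and the
   alternative is one flag away. Fold changes are ratios of linear-scale
   group means; `input_scale = "log2"` converts via \(2^{\Delta}\) when
   the input is already log-transformed.
3. **Control-referenced normalization**: per gene and time, case values
   are centered by the control mean and scaled by the control SD (sample,
   \(n-1\) denominator — used consistently everywhere). This makes
   composite indices comparable across time-points; downstream analysis
   uses case samples only. A zero control SD is an error naming the
   (gene, time) pair so the offending gene can be filtered.

## The synthetic reference study

The generator plants a DNB block inside an equicorrelated-block Gaussian
background. The defaults are the package's reference condition: 200
genes, a 12-gene planted block, 6 time-points with 20 case and 20 control
replicates, background equicorrelation 0.2 in random blocks of ~10 genes,
and at the planted time-point (the 4th) the block switches to
equicorrelation 0.8, a 3-fold SD boost, and ~0 correlation to
non-members. All genes receive a constant case mean shift of 1.5 control
SDs above a unit baseline at *every* time-point, so the fold-change filter
(ratio 2.5) retains them without leaking the planted time to the
optimizer. Sampling uses a latent-factor factorization of the block
covariance, which is positive definite for any equicorrelation in
\([0, 1)\).

Moment conditions are what the composite index measures, so an
equicorrelated Gaussian emulation is sufficient for testing the machinery;
it does not reproduce probe-level noise, platform effects, heavy-tailed
expression, or a mechanistic bifurcation, and passing tests on it say
nothing about annotation quality or biological interpretability on real
arrays.

## Problem sizes used by the test suite

The suite runs the reference recovery experiment at population 100 and 40
generations over 10 seeds, and the null-calibration study (SD boost 1,
within-block correlation equal to background) at population 40 and 15
generations over 200 significance replicates plus 100 full scans. These
sizes are the package's chosen desk-scale experiment; the full defaults
(population 500, 100 generations) behave the same way, only slower. The
acceptance script re-runs the recovery study from scratch.

## Known limitations

* **Optimizer selection bias in the significance test.** The observed
  distance sample comes from *optimized* subsets while the null sample
  comes from random ones, so even on null data (no planted structure) the
  front sits closer to the ideal than its size-matched nulls and the
  one-sided rank test rejects far more often than its nominal level. The
  test is calibrated only in the exchangeable case — when the objectives
  carry no information about subset content — which the suite verifies.
  On real scans the p-value is therefore a *relative* ranking device
  across time-points, not an absolute error rate.
* **Front-size coupling.** With one null per observed solution, the
  smallest achievable exact rank-sum p-value is determined by the front
  size (e.g. 1/20 for a 3-solution front), so times whose fronts collapse
  to a few distinct solutions can never reach the p-values of times with
  rich fronts. Comparing per-time p-values therefore partly reflects
  front cardinality; the per-time table exposes `n_solutions` so this is
  visible.
* **Minimal-subset preference.** The index ratio is scale-free in group
  size while sampling extremes favor small groups: a lucky pair can reach
  a higher \(I_t\) and a lower \(I_{t-1}\) than the full planted module,
  and then Pareto-dominates it. The distance rule consequently tends to
  select compact cores (often 2–4 genes inside the true module) rather
  than the whole module. Raising `min_size` enforces biologically
  plausible module sizes when that is unacceptable.
* The composite index treats the interactome as complete: every gene pair
  contributes to the correlation averages whether or not the pair
  interacts physically. An interactome-restricted variant would need a
  re-derivation of the criteria and is out of scope.
* With replicate counts around 20, the expected absolute correlation of
  independent genes is ~0.18, so \(\mathrm{PCC}_{out}\) never approaches
  zero on finite data; the \(\varepsilon\) floor is a numerical guard,
  not the operating regime.
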