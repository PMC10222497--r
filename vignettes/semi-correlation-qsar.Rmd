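---
title: "Semi-correlation QSAR models from SMILES optimal descriptors"
author: "semicor authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-correlation QSAR models from SMILES optimal descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semicor)
```

## The model

`semicor` builds binary classifiers (active = 1 / inactive = 0) for
molecular endpoints such as drug-induced liver injury directly from SMILES
strings, treating them purely as symbol sequences. No molecular descriptors,
conformers or chemistry perception are involved; the modelling unit is the
**SMILES attribute**: a single token $S_k$, an adjacent pair $SS_k$, or an
adjacent triple $SSS_k$. Pair and triple keys are direction-independent (a
window read backwards maps to the same attribute), because the string
orientation of a SMILES line is arbitrary.

Each attribute carries a real **correlation weight** $CW(\cdot)$, and a
compound's **optimal descriptor** is

$$DCW(T, N) = \sum CW(S_k) + \sum CW(SS_k) + \sum CW(SSS_k),$$

summed over all attribute occurrences (an attribute occurring $k$ times
contributes $k$ times its weight). $T$ is the rarity threshold: attributes
seen in fewer than $T$ distinct active-training compounds are flagged rare,
keep $CW = 0$ forever, and never influence the descriptor; attributes never
seen in the active training set are treated the same way at prediction time.
$N$ is the number of optimization epochs behind the weights.

The endpoint is modelled by **semi-correlation**: an ordinary least-squares
line fitted to the binary labels,

$$y = C_0 + C_1 \, DCW(T, N), \qquad
  \text{active} \iff y \ge 0.5,$$

with the boundary $y = 0.5$ classified active. Regressing a 0/1 response on
a single continuous descriptor is unconventional but deliberate: it keeps
the model a one-dimensional line whose slope, intercept and correlation
coefficient are all interpretable, and classification reduces to a fixed
threshold on the fitted value.

## Four-way splits and the optimization

Compounds are randomly partitioned into four roughly equal sets, each with
one job:

* **active training** (~25%) — builds the vocabulary and fits the weights
  and the regression line;
* **passive training** (~25%) — checks that the weights are not merely
  memorising the active set (it enters the target function);
* **calibration** (~25%) — detects the onset of overtraining;
* **validation** (~25%) — untouched until the end; measures predictivity.

Weights are fitted by a greedy coordinate Monte Carlo search. Per epoch,
every non-rare attribute is visited once in seeded-random order; a visit
proposes $cw' = cw + u$ with $u \sim U(-\delta, +\delta)$, the line is
refitted on the active training set, and the move is kept iff the target
function does not decrease. Two target functions are available:

$$TF_0 = r_{AT} + r_{PT} - |r_{AT} - r_{PT}| \times 0.1, \qquad
  TF_1 = TF_0 + IIC_C \times 0.5,$$

where $r_{AT}, r_{PT}$ are Pearson correlations between observed and fitted
endpoints on the two training sets, and $IIC_C$ is the **index of ideality
of correlation** on the calibration set:

$$IIC_C = r_C \,
  \frac{\min(MAE_C^-,\, MAE_C^+)}{\max(MAE_C^-,\, MAE_C^+)},$$

with $MAE^-$/$MAE^+$ the mean absolute errors of the strictly negative and
the non-negative residuals $\Delta_k = \text{observed}_k -
\text{calculated}_k$ (zeros count to the "+" side). The ratio lies in
$[0, 1]$, so $|IIC| \le |r|$; it rewards fits whose under- and
over-predictions are balanced in magnitude. Two conventions are worth
stating explicitly because the notation is ambiguous in parts of the
correlation-weight literature: the min/max ratio is taken over the two
*non-negative subset MAEs* (the superscripts label the residual sign, they
are not arithmetic negation — a literal negation would make the index
unbounded and sign-flipped); and a perfect fit (both MAEs zero) returns
$r_C$ itself, while a one-signed residual distribution gives $IIC = 0$.

Degenerate proposals (constant descriptor or constant predictions, where a
correlation is undefined) are assigned $-\infty$ and thus always rejected;
this keeps the optimizer total without special cases.

### The overtraining guard

Training correlations rise almost monotonically with epochs, but the
calibration set's quality peaks and then declines — the start of
overtraining. Rather than halting online at a noisy peak, the optimizer
runs all $N$ epochs, records per-epoch histories (target function, $r$ and
MCC for all four sets), and returns the weight snapshot from the epoch
with **maximal calibration MCC** (ties go to the earliest epoch).
MCC is the monitored curve because it is the deployment-relevant quantity
for a hard-threshold classifier; the $r$ histories are recorded alongside.
Validation metrics are logged per epoch for reporting but never feed back:
permuting validation labels changes no weight, no coefficient and no chosen
epoch (this is a unit test).

Note that under $TF_1$ the calibration set participates in the objective
through $IIC_C$, so its peak is no longer a fully independent overtraining
signal; the classic rise-peak-decline pattern is sharpest under $TF_0$.
This mirrors how the two optimization variants behave in published
correlation-weight models, where the IIC-augmented run trades a visible
overtraining signature for better-balanced validation performance.

## The system of self-consistent models

A single random split yields a single model whose validation statistics are
themselves a random outcome. The package therefore trains $k$ models on $k$
independent four-way splits and evaluates **every model on every split's
validation set**, producing a $k \times k$ MCC matrix whose diagonal holds
the ordinary validation results. The off-diagonal mean ± population
standard deviation is the self-consistency summary: a tight dispersion
means the modelling protocol, not a lucky split, carries the performance.
Validation compounds that overlap a model's training material are *not*
excluded from the cross cells — that is the protocol as practised — but the
Jaccard overlap matrix of the validation sets is reported alongside so the
contamination is visible (for independent 25% subsets the expected pairwise
Jaccard index is $1/7 \approx 0.14$). The dispersion is the population
(not sample) standard deviation because the $k(k-1)$ cells are an
exhaustive enumeration, not a sample.

## Tunable parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `T` | rarity threshold (distinct active-training compounds) | 1 | typically 1–3 for real SMILES; see below for synthetic strings |
| `n_epochs` | optimization epochs | 40 | run well past the expected calibration peak; the guard rolls back |
| `step` | half-width of the weight perturbation | 0.1 | larger steps (0.5–1) explore faster on small vocabularies |
| `init_low`, `init_high` | uniform weight initialization | 0.5, 1.5 | nonzero so the initial descriptor is non-degenerate |
| `target` | `TF1` or `TF0` | `TF1` | `TF1` adds the calibration IIC |
| `tf0_penalty` | training-gap penalty | 0.1 | fixed in the target-function definition |
| `iic_weight` | IIC weight in `TF1` | 0.5 | fixed in the target-function definition |
| `seed` | top-level seed | 1 | split/init/move/synthetic streams are derived sub-seeds |

Rarity is counted per compound (document frequency), not per occurrence:
"rare" is about how many training molecules support a weight estimate, and
a weight carried by one molecule is unreliable no matter how often it
repeats within that molecule's string.

## The synthetic-data generator

The generator (`simulate_compounds()`) exists because realistic endpoint
tables of this kind (~1300 drugs with binary hepatotoxicity calls) are
typically not redistributable. It emulates their *statistical* shape, not
their chemistry: random token strings over a 13-token SMILES-style
alphabet, lengths uniform on 10–30 tokens, with a planted linear
structure-activity signal. A compound's true score is the sum of planted
per-token weights over its single-token attributes plus Gaussian noise
(`noise_sd`, default 0.2), and labels are assigned by thresholding the
score at the empirical quantile giving the target active fraction
(default 0.6, the prevalence of the motivating hepatotoxicity table), or
by a logistic Bernoulli draw. Defaults: $n = 1274$ compounds, signal on
five tokens (N +0.8, O −0.8, Cl +1.2, S −1.0, # +0.6).

Planting effects on single tokens only keeps the ground truth
interpretable for parameter-recovery tests while pair/triple machinery is
still exercised (pairs and triples of the planted tokens correlate with
the signal). The strings are *not* chemically valid molecules; the method
under study treats SMILES as symbol sequences, so validity is irrelevant
to computational correctness. Consequently, passing recovery tests shows
the machinery optimizes and generalises as designed — it says nothing
about how much signal real hepatotoxicity data carries, and nothing about
chemistry-dependent failure modes (tautomers, salts, canonicalisation
variants) that real SMILES bring.

### Benchmark settings for synthetic strings

One generator/optimizer interaction deserves emphasis. For real drug
SMILES, vocabulary sizes are large and document frequencies are spread
out, so the customary $T \in \{1, 2, 3\}$ separates rare from non-rare
attributes meaningfully. Synthetic strings drawn from a 13-token alphabet
behave differently: every single token appears in nearly every compound,
while specific triples are scattered thinly. Probe runs across
$T \in \{1, \dots, 60\}$ on the planted benchmark show exactly what the
rarity filter is for: at small $T$ the ~1000-attribute vocabulary lets
the coordinate search overfit the ~100 active-training compounds
(validation MCC ~0.47 at $T = 1$), while requiring attributes in at least
40% of the active-training set (T = 40 at $n = 400$) retains the 13
single-token attributes — where the generator actually plants signal —
and recovery rises to validation MCC ≈ 0.8. The package's synthetic
benchmarks therefore use `T = ceiling(0.4 * n_AT)`, `step = 1`,
`n_epochs = 300`, target `TF1`; this is the package's own empirical-probe
choice of $T$, the same procedure one would apply to any new dataset.

The tests and the acceptance script use these problem sizes: $n = 400$
compounds for replicated recovery/null/overtraining checks (5–10 seeded
replicates each) and $n = 1274$ for the study-scale single run and the
$k = 5$ self-consistent system.

## Numerical choices and degenerate inputs

* OLS coefficients are recomputed after every proposed move from the
  closed-form slope/intercept; zero descriptor variance raises an explicit
  "degenerate descriptor" error at the API level and rejects the move
  inside the optimizer.
* The boundary $y = 0.5$ is classified active (the inequality is
  non-strict by definition).
* Residuals with $\Delta_k = 0$ count to the "+" subset of the MAE split.
* Zero-denominator statistics: sensitivity/specificity are reported as
  `NA` (undefined), MCC as 0 with a degeneracy flag — the usual convention.
* Reported tables round half-up at 4 decimals (so 0.78125 prints 0.7813);
  a plain `round()` would round half-even.
* Pair/triple canonical keys take the lexicographically smaller of the
  forward and reversed joins compared in C-locale byte order, so
  vocabularies are identical across platforms and locales.
* The empty SMILES string tokenizes to an empty profile ($DCW = 0$,
  $y = C_0$) rather than erroring: degenerate compounds are data, not
  exceptions.
* All randomness flows from one integer seed, fanned out into named
  sub-streams (split, init, moves, synthetic), so any run is reproducible
  bit-for-bit from its manifest.

## A worked example

```{r example, eval = FALSE}
library(semicor)

d <- simulate_compounds(n_compounds = 400, noise_sd = 0.2, seed = 1)
cfg <- optimizer_config(target = "TF1", T = 40, n_epochs = 300,
                        step = 1, seed = 1)
run <- run_train(d, cfg, out_dir = "run1")
run$report            # per-set confusion counts and statistics
plot_history(run$fit) # four-set MCC trajectories with the chosen epoch

sys <- run_self_consistent(d, cfg, k = 5, out_dir = "system1")
round(unclass(sys$matrix), 3)
sys$summary           # off-diagonal mean, dispersion, all-cells mean
```

## Known limitations

* The semi-correlation line is a linear probability model; with unbalanced
  classes the fixed 0.5 cut sits off the optimal boundary, which costs
  some MCC relative to a tuned threshold. This is inherent to the method
  definition, not an implementation choice.
* Greedy accept-if-not-worse coordinate search finds good, not optimal,
  weights; runs are deterministic per seed but different seeds land on
  different local optima (validation MCC varies by ~±0.07 on the n = 400
  benchmark).
* Under `TF1` the calibration set is both an optimization signal (via
  IIC) and the overtraining monitor; the returned snapshot can therefore
  be mildly optimistic about calibration-set quality. The validation set
  remains untouched either way.
* No applicability-domain machinery: every compound gets a prediction,
  with unknown-attribute counts as the only flag.
* Cross-split cells of the consistency matrix evaluate compounds that may
  have been in the model's training sets; use the overlap matrix to judge
  how much that matters.
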