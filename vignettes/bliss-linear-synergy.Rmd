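---
title: "Bliss-based linear modeling of sparse drug-combination screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bliss-based linear modeling of sparse drug-combination screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blisscreen)
library(dplyr)
```

## The problem

Large drug-combination screens trade dose coverage for breadth: all pairwise
combinations of on the order of a hundred drugs, across tens of cancer cell
lines, at only two dose pairs, with one well per combination and one well per
single drug ("singlet"). Under that design the classical Excess-over-Bliss
score

$$S_{ij} = V_i \cdot V_j - V_{ij}$$

(with $V$ the viability: treated-well nuclei count divided by the mean
untreated count) is fragile. A single noisy singlet well corrupts the Bliss
expectation $V_i V_j$ for every one of that drug's pairs at once; inactive
drugs whose measured viability drifts above 1 produce spuriously large
scores; and on a noisy assay the score distribution inflates wholesale,
because the score has no accompanying error model.

`blisscreen` implements the remedy this package is organized around: treat
Bliss independence as a *linear model over the whole assay*. On the
working scale $W = -\log_{10} V$, independence is additive,
$W_{ij} = W_i + W_j$, so the $\binom{n}{2}$ combination wells of one assay
(one cell line at one dose) form an over-determined linear system in only
$n$ unknowns — one equation per pair well, two ones per row of the
incidence matrix. Ordinary least squares (no intercept; none is
identifiable or needed, since a global shift is absorbed by the $W_i$)
estimates every singlet from the combination data alone. Measured singlet
wells are *never* used in the fit; they are held out for validation. Each
drug's estimate borrows from its $n-1$ combination wells, so its standard
error shrinks roughly as $\sigma/\sqrt{n/2}$, far below the error of a
single singlet well.

The residual $r_{ij} = W_{ij} - (\hat W_i + \hat W_j)$ is then itself the
synergy score: positive when the combination killed more than independence
predicts (observed viability below the Bliss expectation), negative for
antagonism.

## From residuals to p values

The null model for a residual is Gaussian with mean zero and variance

$$\mathrm{var}_0(i,j) = \mathrm{var}_\mathrm{DMSO} + \mathrm{se}_i^2 + \mathrm{se}_j^2,$$

the unbiased sample variance of the assay's DMSO (vehicle-only) wells on
the $W$ scale — an assay-specific measurement-noise gauge, pooled over the
assay's plates — plus the squared standard errors of the two singlet
estimates. A Gaussian is the natural choice here: the variance terms are
combined additively, which is exact for Gaussian log-scale noise. One-sided
tails give $p_\mathrm{syn} = 1 - \Phi(z)$ and $p_\mathrm{ant} = \Phi(z)$
with $z = r_{ij}/\sqrt{\mathrm{var}_0}$, and Benjamini–Hochberg correction
is applied per assay and per direction, across that assay's pairs (the
family a screener actually scans). A pair is synergistic at level
$\alpha = 0.05$ when $q_\mathrm{syn} < \alpha$; per cell line, a pair
counts as synergistic when either dose is called (`combine_doses()`).

Because the null variance grows with the DMSO spread, a noisy assay
*demands more* of its residuals instead of handing out more calls — the
opposite behaviour of raw Excess-over-Bliss thresholding, whose call count
explodes with noise. The acceptance suite reproduces this contrast on
synthetic assays whose noise is multiplied by five.

Pairs with a very low observed combination viability ($V_{ij} < 0.1$) are
flagged rather than corrected: the log-scale variance of
$\log(V_iV_j/V_{ij})$ may be understated there, and those calls deserve
caution.

## Preprocessing

Raw nuclei counts are normalized per plate: an optional one-iteration Tukey
median polish of the $\log_{10}$ counts over plate rows and columns (row
sweep, then column sweep; re-exponentiated, so adjusted counts stay
positive), then division by the plate's DMSO control value, a 10%-per-side
trimmed mean of the control wells. Zero counts get a pseudocount of 0.5
with a warning. Viabilities are deliberately *not* capped at 1 — capping is
exactly the kind of ad-hoc fix the error model replaces.

One desk-scale caveat, found while validating on synthetic plates and worth
stating plainly: the polish estimates a median per row and per column, and
those estimates carry sampling noise of order
$\sigma_\mathrm{signal}/\sqrt{\text{wells per row}}$. On production-scale
1536-well plates with ~46 occupied wells per row this is small relative to
the spatial artifacts it removes; on the small synthetic plates used in
this package's studies (384-well, ~14 wells per row) it would *add* more
noise than the planted artifacts it removes. The synthetic studies and the
acceptance script therefore run with `polish = FALSE`, while `polish =
TRUE` remains the default for real plate data. For the same reason the
polish is not a no-op on an artifact-free plate (row medians of true
treatment effects are not zero); what holds exactly, and is tested, is
that a *uniform* multiplicative row artifact is removed without disturbing
any viability.

## Scores across cell lines

The absolute synergy score $T_{ij}$ counts the cell lines in which pair
$(i,j)$ is synergistic (dose-combined). Because some drugs are promiscuous
sensitizers — synergizing with nearly everything — $T$ alone over-ranks
them. The specificity score standardizes $T_{ij}$ against each drug's own
synergy profile:

$$Sc_{ij} = \min\!\left(\frac{T_{ij} - \langle T_{ik}\rangle_k}{\mathrm{SD}(T_{ik})_k},\;
\frac{T_{ij} - \langle T_{kj}\rangle_k}{\mathrm{SD}(T_{kj})_k}\right)$$

with $k$ ranging over all partners of the drug (including $j$ itself by
default; `include_self = FALSE` excludes it — the defining text leaves the
partner set ambiguous, and including the pair's own score is the literal
reading). Sample SD ($n-1$) is used; a zero SD contributes a neutral 0
rather than an infinity. Pairs are ranked by $T$ with $Sc$ as tie-break.

## Randomization nulls

Two nulls probe the structure of the synergy "cube" (drugs × drugs × cell
lines):

* `permute_within_cell_line()` shuffles each cell line's calls across
  pairs, conserving per-cell-line totals exactly — the reference for the
  shape of the $T$ distribution.
* `binomial_null_matrix()` conserves each *drug's* promiscuity instead:
  $T'_{ij} \sim \mathrm{Binomial}(N, \mathrm{clip}(p_i + p_j, 0, 1))$, with
  per-drug propensities $p_i \ge 0$ fitted by coordinate descent so the
  expected per-drug totals match the observed ones (the defining text only
  pins "a function of the sum" — the clipped sum is the simplest monotone
  choice that reproduces marginals). When some drugs have zero observed
  synergies the non-negativity constraint binds and the marginals are
  matched only in the least-squares sense; on matrices drawn from the null
  itself the match is exact up to Monte-Carlo error, which is what the test
  asserts.

`high_score_test()` compares the observed number of pairs with $T$ above a
threshold (default 12, chosen for a 40-cell-line screen) against the
binomial null, with the add-one empirical p value
$(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + n_\mathrm{rand})$, so 1000
draws can report at best $p = 1/1001 < 0.001$.

## The synthetic-screen generator

`generate_screen()` builds complete plate tables with the structure the
method assumes: per (cell line, dose) assay, all pair wells, one singlet
well per drug, and DMSO wells, placed in pseudo-random order on as many
plates as needed. Truth lives on the $W$ scale: a per-dose drug effect,
plus a drug × cell-line effect shared between doses (SD 0.15 by default —
without it, singlet profiles would have no cross-dose signal for the
consistency analyses to recover; 0.15 is a realistic heterogeneity scale
for drug response across cancer lines relative to per-dose means of 0.3/0.1
at the standard and fifth-dose levels). Well noise is Gaussian on $W$
(default SD 0.05), singlet wells are three times noisier by default
(modelling the single-well singlet measurements that motivate the method),
and planted synergies/antagonisms add $\delta_W$ to chosen (pair, cell
line, dose) units. `default_screen_spec()` is the package's documented
study condition: 20 drugs, 8 cell lines, both doses (190 pairs per assay),
three planted synergies at $\delta_W = 0.25 = 5\sigma$, one planted
antagonism, one promiscuous sensitizer (40% of its partner × cell-line
units), and mild row/column artifacts.

Because the generator's noise is Gaussian on the log scale, the inference
model is *exactly correct* under it. Passing tests therefore demonstrate
internal correctness and calibration — estimator, error propagation, FDR
machinery, score algebra — not robustness to everything real data does:
count-level (Poisson-like) noise, dose-dependent variance, edge effects
beyond additive row/column terms, or biological correlation between a
drug's synergy partners are all outside what the defaults emulate.

## Numerical choices

* $W = -\log_{10} V$ throughout; any log base is equivalent, one keeps all
  quantities consistent.
* Least squares via QR with a rank check (tolerance at LAPACK defaults);
  a connected pair design always has full column rank, and connectivity is
  checked first with an explicit component listing.
* $R^2$ is reported against the mean-model baseline
  ($\mathrm{TSS} = \sum (W_{ij} - \bar W)^2$) even though the model has no
  intercept — fit quality is only interpretable against that baseline.
* $z = r/\sqrt{\max(\mathrm{var}_0, 10^{-16})}$: the floor turns the
  0/0 of an exactly noiseless assay into $z \approx 0$ while leaving any
  genuine effect on a degenerate assay with an enormous $|z|$.
* Residual degrees of freedom $m - n$ for $\sigma^2$; standard errors from
  $\sigma^2 (X^\top X)^{-1}$.
* Trimming drops $\lfloor n \cdot 0.10 \rfloor$ controls per side.
* Coordinate descent for the binomial propensities: 1-D minimization per
  coordinate on $[0,1]$, sweeps until the objective's relative change is
  below $10^{-8}$ (500 sweeps cap), started from
  $p_i = O_i / (2N(n-1))$.
* All randomized procedures take explicit integer seeds; a master seed
  spawns per-replicate streams.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic screens
at desk scale, chosen as the smallest sizes at which every phenomenon of
interest is visible: 20-drug, 8-cell-line screens (190 pairs per assay) for
power, consistency and scoring studies; 100 replicate screens for the
power/type-I study; 20 replicates for the cross-dose comparison; 1000
draws for randomization nulls; and a single 108-drug design to pin the
full-scale combinatorics (5778 equations). A complete 108-drug, 40-cell-line
analysis is the same code path, just larger.

## Worked example

```{r example, eval = FALSE}
scr <- generate_screen(default_screen_spec(seed = 1))
res <- run_pipeline(list(
  simulate = default_screen_spec(seed = 1),
  polish = FALSE, out_dir = tempfile("screen_results")
))
head(res$ranked)        # planted pairs at the top, promiscuous pairs penalized
fit_summary(res$fits)   # per-assay R^2 and residual variance
```

## Limitations

* Two discrete dose levels as in the motivating screen; no dose–response
  surface modelling (and no Loewe additivity, which sparse designs cannot
  support).
* No robust or weighted regression variants; a grossly contaminated assay
  shows up as a low $R^2$ and a large DMSO variance (the intended QC
  surface) rather than being down-weighted automatically.
* The null variance may be understated for very low combination
  viabilities; such pairs are flagged, not corrected.
* No empirical-Bayes shrinkage of variances and no parametric count-noise
  model.
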