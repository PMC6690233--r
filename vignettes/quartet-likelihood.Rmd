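---
title: "Quartet likelihood under JC69: star trees, continuous gamma rates, and the starless bias"
author: "quartetstar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quartet likelihood under JC69}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(quartetstar)
```

## The model and its state space

`quartetstar` works with exactly four aligned nucleotide sequences (OTUs
S1..S4) under the Jukes–Cantor (JC69) substitution model: equal base
frequencies of 1/4 and a single exchange rate, so the transition
probability along a branch of length $d$ (in expected substitutions per
site) is

$$P_{ii}(d) = \tfrac14 + \tfrac34 e^{-4d/3}, \qquad
  P_{ij}(d) = \tfrac14 - \tfrac14 e^{-4d/3}\ (i \ne j).$$

With four sequences a column can show $4^4 = 256$ patterns, but JC69 is
blind to which nucleotides are involved: patterns collapse into 15
equivalence classes determined solely by how the OTUs are partitioned by
shared nucleotide, grouped as G1 (all four different, 24 raw patterns),
G2 (three distinct nucleotides; 6 classes of 24), G3 (a 3+1 split; 4
classes of 12), G4 (a 2+2 split — the parsimony-informative patterns; 3
classes of 12) and G5 (monomorphic; 1 class of 4).  `pattern_classes()`
lists them in the canonical order that fixes class ids 1..15.

A whole equidistant alignment is therefore described by five integers
`(n1..n5)`: `n2` means each of the six G2 classes occurs `n2` times, and
so on, for a total length of $n_1 + 6n_2 + 4n_3 + 3n_4 + n_5$.  Any such
combination makes all six pairwise Hamming distances equal
($n_1 + 5n_2 + 2n_3 + 2n_4$), which is what "equidistant" means here.
`quartet_alignment()` materialises the canonical alignment;
`as_pattern_counts()` goes the other way from any 4-sequence alignment.
The choice of representative nucleotides is immaterial to every JC69
computation (only the byte-level FASTA output depends on it).

Likelihood is always computed per class and weighted by counts.  This
256-to-15 collapse is the package's central efficiency contract: a full
continuous-gamma evaluation costs at most 15 one-dimensional integrals,
never one per alignment column.

## Trees and likelihood

A quartet is either the *star* tree (four terminal branches $b_1..b_4$
meeting at one node; the internal branch is structurally zero) or one of
three resolved pairings 12|34, 13|24, 14|23 with an internal branch
$b_5 \ge 0$.  The star tree is nested in every resolved topology at
$b_5 = 0$.  Column likelihoods are sums over the internal-node states
(one node for the star, two for a resolved tree); the implementation is
verified in the test suite against a literal brute-force enumeration
whose transition matrices come from the matrix exponential of the rate
matrix, to $10^{-12}$.

Rate heterogeneity across sites is modelled by a mean-one gamma
distribution with shape $\alpha$ (variance $1/\alpha$): the class
likelihood becomes $\int_0^\infty g(r;\alpha)\,L_c(r\,\mathbf b)\,dr$,
marginalised *continuously* — there is no discrete-category
approximation anywhere in the package.

### Numerical choice: the rate integral

The integral is mapped to $(0,1)$ by the quantile transform
$r = Q_\Gamma(u;\alpha)$, which absorbs the gamma density exactly, and
evaluated by a fixed composite Gauss–Legendre rule (12 panels of 16
nodes, graded toward both endpoints).  The quantile transform is the
crucial choice: at $\alpha = 10^4$ the rate distribution concentrates in
a band of width $10^{-2}$ around 1, which defeats generic substitutions
such as $r = u/(1-u)$ but is handled exactly in quantile space.  An
adaptive alternative (`quadrature = "adaptive"`, `stats::integrate` at
relative tolerance $10^{-9}$) is retained for verification; the two
agree to below $10^{-5}$ log-likelihood units for $\alpha \ge 0.01$ and
to about $10^{-2}$ at the extreme lower bound $\alpha = 10^{-3}$, where
the rate distribution is a near-degenerate spike-plus-tail mixture.

## Fitting: bounds, restarts, and multiple optima

`quartet_ml()` maximises the log-likelihood with bounded L-BFGS-B.
Branch lengths live in `[b_min, b_max]` (defaults 0 and 10): an upper
bound is unavoidable for saturated data, whose likelihood increases
towards the equal-frequency supremum as branches grow, and beyond length
10 the change is negligible.  The shape parameter is optimised on a log
scale in `[1e-3, 1e4]`; an estimate at `alpha_max` is reported as "no
detectable rate heterogeneity", mirroring how such fits are customarily
read.  Convergence follows `optim`'s `factr = 1e4` (about $10^{-12}$
relative); fits are exactly reproducible because the restart grid is
deterministic.

The restart grid is deliberately small and structured:

* three symmetric starts — all branches at $\hat d/2$ (half the JC69
  distance implied by the mean pairwise difference proportion), at
  `0.1 * b_max`, and at `0.9 * b_max`;
* for resolved topologies, two additional "stretched cherry" starts
  (one terminal branch doubled, its partner at `b_min`).  These exist
  because the resolved profile surface is *ridged*: for
  within-group-equal counts the maximum is typically a continuum of
  parameter vectors with identical likelihood, and a quasi-Newton run
  from a cherry-symmetric start preserves that symmetry exactly, so it
  can stall on a symmetric stationary point strictly below the ridge;
* for gamma fits, every branch start is crossed with shape starts 1 and
  1000, because the surface separates a heterogeneous optimum (long
  branches, small $\alpha$) from a near-homogeneous one.

### Known limitation: asymmetric star maxima

For pathological G4-enriched combinations the *star* surface itself can
develop asymmetric maxima.  The flagship example `(24, 24, 12, 96, 32)`
has a symmetric stationary point at $b = 1.020276$ with
$\ln L = -2947.793$, but placing one OTU on the central node does
better:

```{r asym}
quartet_ml(c(24, 24, 12, 96, 32), "star",
           control = list(extra_starts = list(c(1.7, 0, 1.7, 1.7))))
# b = (1.694, 0.000, 1.694, 1.694),  lnL = -2947.435
```

The default symmetric grid reports the symmetric solution — the natural
null fit for equidistant sequences, and the one comparable with
published star-tree analyses, none of which report the asymmetric
phenomenon (a symmetric-start optimizer provably never leaves the
symmetric manifold).  When the global constrained maximum is what you
need, supply starts via `control$extra_starts` as above.  The same
ridge-degeneracy means that for such data the branch estimates of
resolved fits are not individually interpretable; compare likelihoods,
not branch vectors.

## The star-vs-resolved test and the starless bias

`star_test()` fits the star tree and all three pairings (each resolved
fit warm-started from the star solution, so
$\ln L_{\text{resolved}} \ge \ln L_{\text{star}}$ by construction) and
computes $2\Delta\ln L$ with a $\chi^2_1$ upper tail.  Because the null
pins $b_5$ to the boundary, the textbook reference is the 50:50 mixture
of $\chi^2_0$ and $\chi^2_1$; the plain $\chi^2_1$ default matches how
the test is conventionally applied, and `boundary_mix = TRUE` switches
to the mixture (halving a positive-statistic p-value).

The bias itself: G4 (2+2) patterns need two independent substitutions on
a star tree but only one on the resolved tree that matches their split,
so an excess of G4 over G3 patterns rewards $b_5 > 0$ even when the
sequences are exactly equidistant and the G4 patterns support all three
pairings equally — a third of them always backs whichever resolved tree
is proposed.  `sweep_informative()` traces the statistic as $n_4$ grows;
holding the other counts fixed it is non-decreasing in $n_4$ (asserted
as a property test).  The companion confounding effect is that an
imposed resolved topology splits the G4 patterns into one-substitution
and two-substitution subsets, manufacturing "rate heterogeneity": on
`(24, 24, 12, 96, 32)` the star fit estimates $\alpha$ at the $10^4$ cap
(none) while fixing $b_5 = 10$ yields $\hat\alpha \approx 1.17$
(strong), with the likelihood still rising as the $b_5$ cap is raised
through 30 and 50.  $\alpha$ is a property of the tree-plus-data fit,
not of the sequences.

Two subtleties surfaced by the test suite are worth recording.  First,
even data simulated on a star tree and symmetrised within groups can
show a tiny positive statistic: a replicate whose sampled G4 count
fluctuates above its star expectation admits a small $b_5 > 0$
improvement that is *identical in all three pairings* (0.005–0.15
log-units in the suite's replicates).  The star tree is always retained
(p > 0.5); the sharp invariant is not "statistic exactly zero" but "no
pairing is preferred", which the tests assert to $10^{-6}$.  Second, the
G1/G5-only combination `(400, 0, 0, 0, 400)` rejects the star tree under
a constant rate ($2\Delta\ln L = 7.12$, $p = 0.0076$; both fitted optima
were cross-checked against an independent pruning implementation) but
not relatively under gamma rates, where both fits degenerate to the
$\alpha$ floor — with no G2–G4 patterns at all, the "heterogeneity"
explanation absorbs most of the conflict.

## Goodness of fit of any single tree model

`pattern_gof()` asks the complementary question: does *any* single
tree-plus-model fit the observed site patterns?  It compares observed
class counts against their expectation under the fitted tree
(`predict(fit, "counts")`) with the likelihood-ratio statistic
$G = 2\sum_c O_c \ln(O_c/E_c)$, and calibrates it by parametric
bootstrap — multinomial draws from the expected class probabilities,
each refitted under the same topology, rate model and bounds (warm
started; `n_boot = 200` by default, seeded).  A bootstrap was chosen
over an asymptotic $\chi^2$ because the effective degrees of freedom
after fitting 4–6 parameters to 15 correlated cells are contested.  On
data simulated from the fitted model the p-values are approximately
uniform (Kolmogorov–Smirnov check in the suite); on the G4-enriched
concatenation the statistic is far beyond every bootstrap replicate,
the operational signature that the data are a mixture of incompatible
tree models rather than any single quartet.

## The simulator

`simulate_quartet()` evolves each site independently: uniform root
state, optional gamma rate multiplier, and exact per-branch transition
sampling (stay with probability $P_{ii}(rb)$, otherwise move uniformly
to one of the other three nucleotides).  This is equivalent in law to
event-level simulation under JC69 and much simpler to verify: the test
suite checks the mean class counts against the package's closed-form
class probabilities, pairwise divergences against
$\tfrac34(1 - e^{-4D/3})$, and saturation towards the multiplicity
proportions.  Replicate $i$ uses seed `seed + i`, so any replicate is
reproducible in isolation.

`symmetrize = TRUE` equalises counts within each of G2/G3/G4 — the
post-processing used to make simulated replicates support the three
pairings exactly equally.  On arbitrary counts `symmetrize_counts()`
errors when a group total is not divisible by the group size, so that
constructed datasets are always exact; the simulator instead passes
`trim = TRUE`, which drops the at most 2+3+2 remainder sites.

What the simulator does *not* emulate: unequal base composition,
transition/transversion asymmetry, indels, ambiguity codes, or
among-lineage rate variation.  Tests passing on simulated data therefore
validate the JC69 machinery, not robustness to real-sequence
complications.

## Problem sizes and defaults used in the test suite

The suite runs quartet fits on the published-style pattern combinations
(alignment lengths 256–2528), 60 simulation replicates of 2528 sites for
the distributional checks, 20 symmetrised replicates for the null
behaviour of the star test, and bootstrap sizes of 39–200 for the
goodness-of-fit calibration — sizes at which every check is exact or has
comfortable Monte-Carlo margins while the whole suite completes in a few
minutes on one CPU.  A constant-rate fit takes well under a second; a
continuous-gamma fit, a few seconds (the 192-node quadrature makes the
15 integrals per evaluation cheap).

## Limitations

Four OTUs and JC69 only: under any model with unequal rates or
frequencies (K80, F84, HKY85, TN93, GTR) the 15-class collapse is
invalid, so the representation — not just the likelihood — would have to
change.  No topology search beyond the three pairings; no standard
errors on branch estimates (the ridge degeneracy makes pointwise
standard errors uninformative exactly where the package is most
interesting); the likelihood-ratio test's boundary correction is offered
but not the default; and `alpha_min = 1e-3` admits near-degenerate rate
mixtures that real analyses may wish to floor at a larger value.
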