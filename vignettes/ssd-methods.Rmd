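---
title: "Methods: specificity, specificity diversity, and the permutation framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: specificity, specificity diversity, and the permutation framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssd)
```

# The model

`ssd` treats a microbiome survey as a landscape of habitats. A habitat is
any host-side grouping of samples — a host species, a host class or
phylum, or a diet type — and every sample belongs to exactly one habitat
at the chosen level. The input is a taxa × samples table of relative
abundances (counts are accepted and normalized per sample first; the
abundance-share term below is only comparable across habitats when each
column sums to 1).

## Species specificity

For taxon $i$ and habitat $h$ with $S^h$ samples, of which $S_i^h$
contain the taxon,

$$\Delta_{ih} = A_{ih} \times B_{ih}, \qquad
  A_{ih} = \frac{S_i^h}{S^h}, \qquad
  B_{ih} = \frac{\langle a_i \rangle_h}{\sum_{h'} \langle a_i \rangle_{h'}},$$

where $\langle a_i \rangle_h$ is the arithmetic mean relative abundance
over **all** samples of $h$, zeros included. $A$ is prevalence
(distribution), $B$ is the habitat's share of the taxon's total mean
abundance. $\Delta \in [0,1]$: 1 is an extreme specialist (present in
every sample of $h$, absent elsewhere), an extreme generalist scores
$1/H$, and for any taxon $\sum_h \Delta_{ih} \le 1$ with equality iff
prevalence is 1 wherever the taxon has positive share.

Assumptions worth noting: specificity needs *alternative* habitats
($H \ge 2$ is enforced); presence is abundance strictly above a
`detection_threshold` that defaults to 0 (no minimum-abundance cutoff —
a configurable flag exists because meta-analyses often want one); and
zeros count toward the habitat mean, which is the literal reading of the
definition and the one adopted here.

## Specificity diversity

The specificity values of an assemblage are summarised by Hill numbers of
their relative values $\lambda_i = \Delta_i / \sum_i \Delta_i$:

$${}^qSD = \Big( \sum_{\lambda_i > 0} \lambda_i^{\,q} \Big)^{1/(1-q)},
  \qquad {}^1SD = \exp\Big(-\sum \lambda_i \ln \lambda_i\Big).$$

$q$ is a non-negative real; the default reporting grid is the integers
0–4. At $q = 0$ SD is the richness of positive-specificity taxa; larger
$q$ down-weights low-specificity (generalist or rare) taxa. SD is read as
a proxy for compositional heterogeneity from the specificity
perspective.

# The permutation tests

## SP test

For a treatment pair $(A, B)$ with $m$ and $n$ samples, specificity is
recomputed with $H = 2$ over exactly those two groups (not sliced from a
landscape-wide matrix), the per-taxon observed statistic is
$\Delta_i = |\Delta_{Ai} - \Delta_{Bi}|$, and the null is built by
pooling the $m + n$ samples, re-splitting them at random into simulated
groups of the original sizes `n_perm` times (sampling with replacement
from the split space), and recomputing both specificity lists. The
pseudo-p is $T/\texttt{n\_perm}$ with $T$ the count of permutations whose
simulated difference **strictly** exceeds the observed one. Taxa are
classified five ways (unique in A/B: significant with the other side's
$\Delta = 0$; enriched in A/B: significant with both sides positive;
otherwise indifferent), by default on Benjamini–Hochberg-adjusted
q-values (`use_fdr = FALSE` gates on raw pseudo-p instead).

### Tie handling and calibration — read this before trusting p-values on sparse taxa

The strict-exceedance, uncorrected $T/\texttt{n\_perm}$ rule is the
default because it is the stated procedure this package implements. It
is, however, structurally anti-conservative for taxa detected in very
few pooled samples: a taxon present in exactly one of the pooled samples
yields the *same* $|\Delta_A - \Delta_B|$ under every split, so every
permutation ties the observed value, $T = 0$, and the pseudo-p is 0 no
matter the data. Taxa present in two or three samples are inflated for
the same reason (the acceptance suite measures the stratified null
rejection rates and leaves the calibration criterion red on purpose).
Two mitigations ship behind flags, both off by default:

* `midp = TRUE` counts ties as half-exceedances; on the package's own
  null generator this restores the nominal type-I rate (the test suite
  asserts this).
* `plus_one = TRUE` reports $(T+1)/(\texttt{n\_perm}+1)$, the standard
  never-zero correction.

A related edge case: two treatments consisting of the same single sample
each give an all-tied permutation distribution, hence pseudo-p 0 under
the strict rule (0.5 under mid-p) — but every taxon is still classified
indifferent because the two specificity lists coincide.

## SDP test

The assemblage-level test compares $|{}^qSD_A - {}^qSD_B|$ for six
categories: the four US/ES catalogues from the SP test, their union
("significant"), and all taxa. Category membership is **fixed** from the
observed classification; each permutation re-splits samples and
recomputes only the specificity lists and the two Hill numbers on that
fixed membership. (Re-classifying inside each permutation would make the
categories themselves random sets and the statistic ill-defined across
iterations; fixing membership is the documented choice.) At $q = 0$ the
US and ES rows are structurally trivial — a US category's absent side
has richness 0, an ES category has equal richness on both sides — and
are flagged `trivial` rather than suppressed. Empty categories produce
`applicable = FALSE` rows. FDR is applied per test family: across taxa
within the SP test, across category × order cells within the SDP test,
separately for each comparison pair.

## Reproducibility mechanics

All permutation functions take a `seed`; the same seed reproduces
results bit-for-bit, and `run_comparisons()` derives pair $k$'s seed as
`seed + k`. Pooled samples are canonically ordered by sample id before
splits are drawn, which makes label swap ($A \leftrightarrow B$ with
equal group sizes) an exact symmetry: pseudo-p values are unchanged and
categories swap. With unequal sizes the first-$m$/last-$n$ split rule
breaks exactness and the symmetry holds only in distribution.

# The PT–SD power law

Host evolutionary age (phylogenetic timeline, million years; larger =
more ancient) is modelled against per-host specificity diversity as
$PT = a \cdot SD^{\,b}$, fitted by OLS on natural logs:
$\ln PT = \ln a + b \ln SD$. Per-host SD is the Hill number of the
host's column of the host-species-level specificity matrix; the default
order is $q = 1$ (the Shannon effective number weights all
positive-specificity taxa without the richness term's sensitivity to
singletons), with a flag for 0–4. Fitting is done per diet group plus a
combined fit. Pairs with non-positive PT or SD are excluded (logs are
undefined) and reported; fewer than 3 usable pairs is an error. A
negative fitted $b$ means more modern hosts carry higher specificity
diversity.

# Specificity networks

Either taxa (rows, correlated across habitat columns) or habitats
(columns, correlated across taxa) become nodes. Taxa are first filtered
by occurrence — positive specificity in at least `min_count` habitats,
or `ceiling(min_fraction * H)` when a fraction is given (so 5% of 318
habitats means ≥ 16; ceiling is the documented convention). For every
pair, Spearman's $\rho$ is computed on average ranks; two-sided p-values
use the large-sample $t$ approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$, with an exact-distribution fallback
(via `stats::cor.test`) selectable for ≤ 9 observations. $|\rho| = 1$ is
assigned p = 0 rather than NaN. Pairs involving a constant vector have
undefined rank correlation and are skipped with a report. BH-FDR is
applied across all tested pairs and edges with $q \le \alpha$ are kept
with their sign. The PN ratio is positive/negative edge counts, `Inf`
when no negative edges exist, 0 when only negative edges exist, and `NA`
for an edgeless network. Core/periphery layout is out of computational
scope; node degree is exported so external tools can build such views.

# What the synthetic generators emulate — and what they do not

`generate_null()` draws, independently of habitat, a per-taxon detection
probability (uniform on 0.2–0.8 by default) and lognormal abundances
(per-taxon location $\sim N(0,1)$, scale 1), then normalizes per sample.
Lognormal abundance with partial detection reproduces the strongly
left-skewed specificity histograms seen in real surveys, and modelling
detection separately from abundance lets the planted generator
manipulate prevalence ($A$) and share ($B$) independently, mirroring the
factorisation of $\Delta$. `generate_planted()` adds unique taxa
(prevalence 1 in their target habitat, absent elsewhere) and enriched
taxa (present everywhere, target-habitat abundance × `fold`, default 8),
targets assigned round-robin. `generate_ptsd()` draws SD log-uniformly
on [1, 100] and applies the power law with lognormal noise
(σ = 0.3 default, the regime in which slope recovery within 2 SE is
expected ~95% of the time).

What they deliberately do **not** model: sequencing-depth effects and
count compositionality, taxon–taxon correlation structure, overdispersed
detection, contamination, or realistic taxonomies. A green test on this
generator therefore establishes correctness of the algorithms under a
clean factorised world, not robustness to real 16S artefacts.

# Numerical choices and degenerate inputs

* Zero-total taxa (mean abundance 0 in every habitat) would make $B$
  0/0; their $\Delta$ is set to 0 everywhere and they are listed in
  `zero_total`, so entropy code never sees NaN.
* All-zero samples are left unnormalized, warned about, and reported —
  dropping them is left to the caller (the behaviour is a convention,
  not a rule inherited from the method's definition).
* $0 \ln 0 := 0$; zero-$\lambda$ terms are dropped from Hill sums; an
  all-zero assemblage has ${}^qSD = 0$ at every $q$ so that empty
  treatment sides (the unique-species richness logic) stay
  representable. Within $|q - 1| < 10^{-10}$ the Shannon limit is used.
* BH adjustment is computed by explicit step-up (sort, $p \cdot m /
  \text{rank}$, cumulative minimum from the top, cap at 1) and is tested
  against `stats::p.adjust` as an independent oracle.
* Habitat order is lexicographic and fixed once per run; all matrices,
  partitions and permutation streams inherit it.

# Known limitations

* Only pairwise ($H = 2$) tests are provided; no omnibus multi-group
  test is defined by the framework.
* The strict-tie pseudo-p default is anti-conservative for sparse taxa
  (see above); users comparing small groups should prefer `midp = TRUE`
  or pre-filter singletons, and should treat p = 0 calls on taxa seen in
  ≤ 2 samples as artefacts of discreteness.
* OLS on the log–log scale ignores host phylogenetic non-independence;
  no PGLS or independent-contrasts variant is attempted.
* The Spearman $t$ approximation is crude below ~10 observations; the
  exact fallback exists but is delegated and slow for many pairs.
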