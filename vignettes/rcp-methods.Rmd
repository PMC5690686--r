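---
title: "Quantifying concordance preference in double-stranded methylation patterns"
author: "rcpmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying concordance preference in double-stranded methylation patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcpmeth)
```

## The model

Hairpin-bisulfite sequencing covalently links the two strands of a DNA
molecule before bisulfite conversion, so a single read reports the
methylation state of both cytosines of each CpG/CpG dyad. A dyad is
observed in one of three states: fully methylated (frequency $M$),
hemimethylated ($H$, a methyl group on exactly one strand), or
unmethylated ($U$). Because the parent and daughter strands of a
recently replicated molecule are separated by exactly one round of
replication, the balance of these states carries information about how
faithfully methylation is copied across replication.

The Ratio of Concordance Preference is

$$\mathrm{RCP} = \frac{2\sqrt{MU}}{H}
             = \frac{\sqrt{U\,(U + 2m - 1)}}{1 - U - m},$$

where $m = M + H/2$ is the overall methylation frequency of CpG
cytosines. The two forms are algebraically identical because
$M = U + 2m - 1$ and $H = 2(1 - U - m)$. Squaring gives
$\mathrm{RCP}^2 = 4MU/H^2$, the classical Hardy–Weinberg
disequilibrium ratio if the three dyad states are read as the
genotypes of a two-allele locus. The interpretation follows directly:

* $\mathrm{RCP} = 1$: methyl groups are placed as if at random —
  either genuinely random placement, or a balance of concordance- and
  discordance-preferring processes;
* $\mathrm{RCP} > 1$: the system prefers concordant dyads, the
  signature of conservative, maintenance-like methylation (Dnmt1-type
  activity);
* $\mathrm{RCP} < 1$: the system prefers discordant dyads
  (dispersive), as in passive demethylation where hemimethylation
  accumulates;
* $\mathrm{RCP} \to \infty$ (all methyl in fully methylated dyads) and
  $\mathrm{RCP} = 0$ (all methyl in hemimethylated dyads) are the two
  extremes, and both are legal return values of `rcp()`.

RCP is undefined when $m = 0$ or $m = 1$: a completely unmethylated or
completely methylated region contains no information about placement
preference, and `rcp()` raises an error rather than returning a value.

The pair $(m, U)$ carries the full information of $(M, H, U)$ and is
the coordinate system used for visualization. At a given $m$, $U$ is
confined to the band between the dispersive boundary
$U = \max(1 - 2m, 0)$ and the conservative boundary $U = 1 - m$; the
random-placement curve $U = (1 - m)^2$ runs between them
(`regionBoundaries()`). Curves of constant RCP (`rcpContour()`) foliate
this band; `uFromMRcp()` inverts the contour equation
$(r^2 - 1)U^2 - (2(1-m)r^2 + 2m - 1)U + r^2(1-m)^2 = 0$, keeping the
root inside the feasible band (when both qualify, at the degenerate
$r = 1$ edge, the smaller root is kept — continuous with the linear
$r = 1$ case).

```{r geometry}
rcp(dyadFreqs(0.25, 0.5, 0.25))  # on the random curve
rcp(dyadFreqs(1, 1, 1) / 3)      # 2-fold concordance preference
regionBoundaries(0.4)
```

## Input data and its handling

Pattern files are TSV with one row per sequenced molecule:
`read_id`, `sample_id`, `locus`, `batchstamp`, `barcode`, and a
dyad-state string over `F` / `T` / `B` / `U` / `.`. The batchstamp
(experiment tag) and barcode (molecule tag) are encoded in the hairpin
linker; reads sharing `(batchstamp, barcode, locus)` are PCR
redundancies, and `deduplicateReads()` keeps the first occurrence —
a deterministic, order-stable policy chosen over consensus collapsing
because it requires no tie-breaking rules and never fabricates a
pattern that was not observed. Hemimethylation orientation (`T` vs
`B`) is preserved on input for potential strand-asymmetry analyses but
collapsed by `countDyads()`, and missing dyads (`.`, partial
double-stranded patterns) are skipped in all tallies, with the missing
fraction reported on parse. Loci are opaque labels; no genomic
coordinate handling is attempted.

Dyad-count tables (columns `sample_id locus n_full n_hemi n_unmeth
n_reads failed_rate inapprop_rate`) are the entry point when only
tallies are available; they carry their conversion-error rates along.

## Conversion-error correction

Bisulfite conversion misreads cytosines in two directions: *failed*
conversion leaves a truly unmethylated cytosine looking methylated
(rate $f$), and *inappropriate* conversion turns a truly methylated
cytosine into an apparently unmethylated one (rate $c$). The package
models misreads per cytosine, per strand, independently and
strand-symmetrically; the two strands of a dyad then combine into a
3×3 row-stochastic matrix over `{FULL, HEMI, UNMETH}`
(`errorMatrix()`). For example the truly unmethylated row is
$(f^2,\; 2f(1-f),\; (1-f)^2)$.

Correction (`correctFreqs()`) inverts this matrix on observed
frequencies; the matrix is invertible whenever $f + c < 1$. Because
errors scatter concordant states into hemimethylation, uncorrected
data are biased toward $\mathrm{RCP} = 1$ — correction matters most
for strongly conservative loci. With sampling noise, the algebraic
inverse can leave the frequency simplex; negative entries are clipped
to zero and the vector renormalized, with a warning. This projection
is idempotent and keeps the corrected point interpretable. Correction
operates at the dyad level, on frequencies rather than counts:
count-level uncertainty is instead handled by resampling whole reads
and correcting each resample, which keeps the correction itself
deterministic. Rates are always user-supplied (from unmethylated or
M.SssI-treated controls); the package never estimates them
internally.

## Inference

Two sampling models are supported, and the distinction is real in the
data: dyads on one molecule are correlated, so treating them as
independent understates uncertainty.

**Read-level BCa bootstrap** (`bootstrapRcp()`). Whole reads are
resampled with replacement; each resample is tallied, corrected, and
reduced to RCP. The confidence interval applies the bias-corrected and
accelerated adjustment: the bias constant $z_0$ comes from the
position of the plug-in estimate in the bootstrap distribution, the
acceleration $a$ from a leave-one-read-out jackknife. Both are
computed on $\log \mathrm{RCP}$ — the natural scale for a ratio whose
bootstrap distribution can include $0$ and $\infty$; the percentile
mapping itself is invariant under monotone transforms, so this choice
affects only the acceleration. The read is also the jackknife unit,
consistent with the read being the independent sampling unit. The
bias-corrected point estimate is the BCa-adjusted bootstrap median.
Resamples with undefined RCP are dropped and counted (warning above
10% dropped, error when all are). Defaults: `nBoot = 10000`,
`level = 0.95`; the seed has no default in the API so that scripted
analyses are forced to pin it (the command-line wrapper draws and logs
one).

`testRcpVsNull()` turns the bootstrap spread into a test of
$H_0: \mathrm{RCP} = r_0$ using the normal approximation on
$\log \mathrm{RCP}$: the statistic is
$\log(\hat r / r_0) / \widehat{se}(\log \mathrm{RCP})$. Working on the
calibrated normal scale, rather than counting bootstrap exceedances,
is what makes p-values far below the resampling resolution (such as
$10^{-16}$) representable.

**Independent-dyad likelihood** (`likelihoodCi()`, `mlct()`). Dyad
counts are treated as multinomial; the cell probabilities are
parameterized by $(m, r)$, pushed through the error matrix, and the
log-likelihood is profiled over $r$ (maximizing over $m$ at each
$r$). The CI is the profile-deviance set
$\{r : 2[\ell_{\max} - \ell_p(r)] \le \chi^2_1(\text{level})\}$, with
endpoints located by bracketed root-finding on $\log r$. The MLE
equals the corrected plug-in frequencies whenever the algebraic
correction stays on the simplex; otherwise a Nelder–Mead refinement is
run. A zero count in a concordant cell pins the estimate to $r = 0$
(and a zero hemimethylated count to $r = \infty$), producing a
one-sided interval that is flagged rather than silently truncated.

The maximum-likelihood comparison test (`mlct()`) is the likelihood
ratio with one degree of freedom: one-sample, $r = r_0$ with $m$ free
versus both free; two-sample, a shared $r$ (each sample keeping its
own $m$) versus free $r$ per sample. Leaving $m$ free per sample under
the null is deliberate: the scientific hypothesis is about placement
preference, not methylation level, and samples routinely differ in
$m$. When a zero cell makes the $\chi^2$ approximation unreliable, the
p-value falls back to a parametric bootstrap under the fitted null
(flagged `parametric_bootstrap`).

**Permutation comparison** (`permutationTest()`). Two read sets are
compared by $|\log \mathrm{rcp}_A - \log \mathrm{rcp}_B|$ on corrected
frequencies, with the null built by reshuffling whole reads between
groups (sizes preserved), and
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_\text{kept})$.

**Replicates** (`heterogeneityTest()`, `poolReplicates()`). The
heterogeneity test is the multinomial likelihood ratio of one shared
dyad-state distribution against free distributions — the G-test of
independence on the $k \times 3$ table, $df = 2(k-1)$. Equality of the
full distribution is stricter than equality of RCP; the stricter null
is used deliberately as a conservative gate: pooling is refused when
heterogeneity is detected at $p < 0.05$ unless forced, and the refusal
carries the test result. Pooled counts are element-wise sums, and the
pooled RCP is asserted to lie between the extreme replicate RCPs.

## The simulator

`simulateReads()` generates hairpin reads with known truth for
validation and power analysis. Collapsed dyad states follow a
stationary first-order chain whose stationary distribution is the
target frequencies (from `targetFreqs(m, r)`) and whose kernel is
$(1-\rho)\,\pi + \rho\,I$: a one-parameter "sticky" chain, the
simplest mechanism that creates the within-read dependence the
read-level bootstrap exists to handle, with $\rho = 0$ recovering
independent dyads. Hemimethylated dyads are assigned top/bottom
orientation symmetrically (the analysis collapses orientation, so no
strand bias is modeled). Conversion errors are injected per strand at
the configured rates, so observed frequencies converge to
`applyErrors(truth, rates)`. Barcodes are unique random strings over
`{A, G, T}` — non-cytosine nucleotides, which bisulfite treatment
leaves intact — and the batchstamp equals the sample id.

What the simulator does *not* emulate: enzyme kinetics (Dnmt1/Dnmt3
processivity, replication timing), sequence-context effects, locus
heterogeneity within a sample, PCR amplification bias beyond exact
duplicates, and read-length variation. Tests passing on simulated data
therefore validate the statistical machinery — estimator calibration,
error-correction algebra, test size and power — not the biological
fidelity of any mechanistic model.

## Numerical choices

* Simplex and feasibility tolerance: $10^{-9}$ throughout;
  frequencies within tolerance are renormalized on construction,
  beyond it rejected.
* Contour inversion selects the quadratic root inside the feasible
  band; ties (the $r = 1$ edge) take the smaller root.
* Profile optimizations use `optimize()` on $m \in (10^{-7},
  1-10^{-7})$ with tolerance $10^{-10}$; CI endpoints use `uniroot()`
  on $\log r$ with doubling brackets (60 doublings before declaring a
  boundary).
* `minFractionForRcp()` bisects to $10^{-6}$ after verifying
  monotonicity of the pooled RCP on a 21-point grid of the instance.
* The BCa bias proportion uses the half-tie convention
  $(\#\{b < \hat\theta\} + \tfrac12\#\{b = \hat\theta\})/B$, clamped
  away from 0 and 1 by $1/(B+1)$; bootstrap quantiles use the default
  type-7 definition.
* Degenerate inputs: empty read sets tally to zero counts; estimation
  refuses totals below 3 dyads; `m = 0` or `1` raises everywhere RCP
  is evaluated.

## Validation scale

The shipped test suite validates calibration by simulation at the
study conditions used throughout: coverage of the 95% bootstrap CI at
$(m = 0.4, r = 5)$ with 500 reads of 4 dyads over 300 simulations
(93–97% required), MLCT size at the $r = 1$ null with 400 dyads over
2,000 simulations (rejection rate within [0.035, 0.065]), error-model
round trips over 1,000 random frequency–rate pairs, and
goodness-of-fit of injected errors at $10^5$ dyads. These sizes give
binomial standard errors well inside the asserted bands while keeping
the default `testthat` run under a minute.

## Limitations

* Conversion rates are treated as known constants; their sampling
  uncertainty is not propagated.
* Per-strand asymmetric error rates and hydroxymethylation are out of
  scope.
* The likelihood route assumes independent dyads; with strong
  within-read correlation its intervals are anti-conservative, and
  the bootstrap route should be preferred (the test suite asserts the
  widening is detectable).
* Two-dimensional $(m, U)$ confidence regions are not drawn; intervals
  are reported on RCP only.
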