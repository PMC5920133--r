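---
title: "Classifying metabolite associations by regulatory layer: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying metabolite associations by regulatory layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tppc)
```

## The question and the model

Metabolite levels are shaped both by transcription (enzyme abundance
follows mRNA) and by mechanisms downstream of it — allosteric inhibition,
substrate competition, covalent enzyme modification. When two metabolites
co-vary across conditions, it is useful to ask *through which layer* the
coupling runs. `tppc` operationalizes this with partial correlation:
the per-sample scores of the first $p$ principal components of the
transcript matrix serve as a compact surrogate for "transcriptional
state", and the correlation of each metabolite pair is re-examined after
that surrogate is partialled out.

For a pair $(X, Y)$ with controls $V = \{Z_1, \dots, Z_p\}$ the order-$p$
partial correlation satisfies the recursion

$$
r_{XY \cdot V} \;=\;
\frac{r_{XY \cdot V \setminus Z} - r_{XZ \cdot V \setminus Z}\,
      r_{YZ \cdot V \setminus Z}}
     {\sqrt{\big(1 - r^2_{XZ \cdot V \setminus Z}\big)
            \big(1 - r^2_{YZ \cdot V \setminus Z}\big)}},
\qquad Z \in V,
$$

with the Pearson correlation as its order-0 base case. Three statistics are
computed per pair: $r_{XY}$ (Pearson), $r_{XY\cdot V}$ (partial), and the
difference $d = |r_{XY} - r_{XY \cdot V}|$. Significance of each comes from
a component-wise permutation null (below), with Benjamini–Hochberg
adjustment within each statistic family, and pairs are classified:

* **TPC** — $q_{\text{pearson}} \le \alpha$, $q_{\text{partial}} > \alpha$,
  $q_{\text{diff}} \le \alpha$: the association collapses when
  transcriptional variance is removed.
* **PPC** — $q_{\text{partial}} \le \alpha$, $q_{\text{diff}} \le \alpha$:
  the association survives. (Optionally also
  $q_{\text{pearson}} \le \alpha$ via `ppc_require_pearson`; the default
  leaves it off, taking the partial-correlation condition as the defining
  one.)

Because TPC requires the partial correlation to be *non*-significant and
PPC requires it significant, the two sets are disjoint by construction.

The identifying assumption is that the leading transcript PCs capture the
bulk of biologically relevant transcriptional co-variation. Nothing in the
construction attributes a TPC call to specific genes, and no causal
direction between the metabolites is implied.

## Equivalent formulations, used as mutual checks

Three algebraically identical routes to the partial correlation are
implemented:

1. the recursion above (`partial_correlation`), eliminating controls in
   stored order, last first — the reference implementation;
2. residual regression (`partial_correlation_oracle`): Pearson correlation
   of the residuals of $X$ and $Y$ after least-squares projection on the
   controls plus intercept;
3. matrix inversion (`partial_correlation_inverse`):
   $-P_{12}/\sqrt{P_{11}P_{22}}$ from the inverse correlation matrix of
   $(X, Y, V)$.

The all-pairs path (`partial_pairs`) conditions the metabolite correlation
matrix on the control block through the Schur complement
$R_{MM} - R_{MV} R_{VV}^{-1} R_{VM}$, rescaled to unit diagonal — one small
matrix inversion per dataset instead of a recursion per pair. Note this is
*not* the same as inverting the full joint correlation matrix of all
metabolites plus controls: the full inverse would condition every pair on
all other metabolites as well, which is a different (Gaussian graphical
model) quantity. The test suite enforces agreement of all formulations to
$10^{-8}$ on random instances with up to three controls, and
order-invariance of the recursion over all permutations of three controls
to $10^{-10}$.

## Choosing the number of components

`select_num_pcs()` reports three classical retention criteria:

* **Broken-Stick**: retain the leading run of components whose proportion
  of variance exceeds $b_i/p$ with $b_i = \sum_{k=i}^{p} 1/k$ (the expected
  ordered segment lengths of a randomly broken unit stick; the $b_i$ sum
  to $p$). The comparison uses $p$ = number of variables, so for data with
  more variables than samples the observed proportions are compared against
  a stick broken into more pieces than there are estimable components.
* **Kaiser–Guttman**: eigenvalues strictly above the mean eigenvalue. The
  mean is taken over all $p$ variables (the rank-truncated tail of exact
  zeros included), so for correlation PCA it is exactly 1 and the criterion
  is "eigenvalue above 1" regardless of the variables/samples ratio.
* **Horn's parallel analysis**: each variable's values are independently
  permuted across samples (1,000 randomizations by default), eigenvalues
  are recomputed, and a component is significant when its observed
  eigenvalue strictly exceeds the 99th percentile of its own rank's null
  distribution. Only the leading consecutive run counts — standard
  parallel-analysis practice; allowing gaps would retain components whose
  larger-eigenvalue predecessors already failed.

The pipeline default is a fixed $p = 3$, a compromise between the
transcriptional variance captured and run time; the criteria typically
bracket it (Broken-Stick and Horn are conservative, Kaiser–Guttman
over-counts under heteroscedastic noise). When `n_pcs = NULL` the choice
falls back to the maximum of the three counts, floored at 1.

PCA itself standardizes variables by default (correlation PCA):
Kaiser–Guttman is classically stated on the correlation matrix and
transcript scales are heterogeneous after typical upstream normalizations.
Eigenvalues and scores come from the SVD of the centered/scaled
samples-by-variables matrix with divisor $n-1$, which is numerically stable
when variables vastly outnumber samples. Zero-variance variables cannot be
z-scored and are dropped with a warning — never imputed.

## The permutation null

"Component-wise" permutation shuffles every variable of *both* layers
independently across samples. This destroys metabolite–metabolite and
transcript–metabolite dependence simultaneously while preserving each
variable's marginal distribution, which makes it a valid joint null for all
three statistics at once; the PCA is refit on the permuted transcripts in
every permutation so the controls are as random as the null pretends. The
alternative reading — permuting only the metabolite layer against the fixed
observed PCs — is available as `permute_layers = "metabolites"` but not the
default, since it tests a narrower hypothesis (independence of metabolites
from each other and from the *observed* components).

Per pair, the empirical two-sided p-value is
$p = (1 + \#\{|t^{null}| \ge |t^{obs}|\})/(B + 1)$ — positively biased,
never zero, with floor $1/(B+1)$. Null distributions are kept per pair
rather than pooled across pairs, since pooling assumes an exchangeability
across heteroscedastic metabolite pairs that real data do not offer. BH is
applied separately within each family (Pearson, partial, difference),
matching the three separate decision conditions. The difference statistic
is tested two-sided on $|d|$; a signed one-sided version would presuppose
that partialling can only shrink correlations, and both directions of
change are routinely observed.

Determinism: every permutation's RNG state is derived from the master seed
and the permutation counter (`seed`, counter → 32-bit substream seed), so
results are bit-identical for a given configuration regardless of execution
order. Collinearity failures inside a permutation are caught, the
permutation is redrawn, and the redraw count is reported (a rate above 1%
warns).

## The synthetic benchmark

`synthetic_spec()` describes the generative model the package uses to test
itself:

| parameter | default | meaning |
|---|---|---|
| `n_samples` | 60 | shared samples (typical paired designs run 40–90) |
| `n_transcripts` | 300 | transcript variables |
| `n_metabolites` | 32 | metabolite variables |
| `n_factors` | 3 | rank of the transcript latent structure |
| `n_tpc_pairs`, `n_ppc_pairs` | 8, 8 | planted couples per label |
| `loading_scale` | 1 | sd of transcript factor loadings |
| `coupling_strength` | 0.85 | coefficient of the shared signal in a planted metabolite |
| `noise_sd` | 0.4 | sd of transcript and planted-metabolite noise |

Transcripts are `loadings × factors + noise`. A planted TPC couple shares a
unit-variance random linear combination of the factor rows; a planted PPC
couple shares a fresh latent vector independent of the factors; all other
metabolites are independent standard normals (unit variance, matching the
planted metabolites' total variance of $0.85^2 + 0.4^2 \approx 0.88$).
Planted couples occupy disjoint metabolites, which is why the default
metabolite count is 32: with 16 planted couples, $2 \times 16$ metabolites
are needed, and 32 is the smallest count that accommodates them.

Two things real data have that this generator deliberately does not:
heavy-tailed or skewed abundance distributions (Gaussian throughout —
Pearson machinery is the object under test, not its robustness), and
structured designs (time series autocorrelation, condition blocks, batch
effects). Passing the synthetic benchmark therefore demonstrates the
statistical logic of the pipeline under its own assumptions, not
performance on any particular measurement platform.

One structural property of the generator deserves emphasis: with 8 TPC
couples drawn from a rank-3 factor space, the shared signals of *different*
couples cannot be orthogonal — the cosine between two random directions in
$\mathbb{R}^3$ is uniform on $[-1, 1]$ — so metabolites from different TPC
couples are genuinely correlated through transcription. The pipeline
correctly classifies many of these cross-couple pairs as TPC; against the
planted-couples-only truth they count as false discoveries, which is a
labelling artifact of the benchmark rather than an error of the method.

## What the difference test can and cannot detect

The PPC rule requires the Pearson-vs-partial difference to be significant.
For a pair whose coupling is *independent* of the transcript components,
that difference is structurally tiny: removing $p$ near-orthogonal
directions perturbs a sample correlation by roughly
$a^2(1 - r)$ per control, where $a \sim n^{-1/2}$ is the chance correlation
between the pair's shared signal and a component — order $1/n$. The
permutation null of the same statistic, however, is built from *independent*
pairs, where the perturbation terms $r_{XZ} r_{YZ}$ do not share a common
factor and accumulate to a visibly wider distribution. The observed
difference for a true post-transcriptional pair therefore sits deep inside
its null, and the difference condition essentially never fires for exactly
the pairs the PPC rule is meant to capture on this generator. On the
synthetic benchmark the package consequently recovers planted
transcriptional couples but not planted post-transcriptional ones — the
recovery metrics reported by `scripts/acceptance.R` and the test suite show
this honestly. Users applying the PPC rule should be aware that its
difference condition acts as a strong filter; `ppc_require_pearson` and the
q-value columns in the pair table allow downstream re-analysis under
relaxed rules.

A related resolution effect: with $B$ permutations the smallest possible
p-value is $1/(B+1)$, and after BH adjustment over $m$ pairs a pair at the
floor has $q \ge m/(k(B+1))$ where $k$ is the number of pairs at the floor.
At $B = 500$ and $m \approx 500$ pairs, $\alpha = 0.01$ is reachable only
if $k \gtrsim 100$ pairs sit at the floor simultaneously. Small permutation
counts are fine for exploration but the production default of
$B = 5000$ is needed for the FDR machinery to have resolution at
$\alpha = 0.01$; this is why the worked example in the README uses 5,000
permutations while the automated checks, which run many pipeline fits, use
500 and interpret the results accordingly.

## Numerical and interface choices

* Collinearity guard: any $(1 - r^2)$ denominator factor below $10^{-12}$
  (or a conditional variance below $10^{-12}$ in the Schur route) raises an
  error naming the offending variable, instead of silently dividing by
  almost-zero. Results are clamped to $[-1, 1]$ against rounding overshoot.
* Degrees of freedom: order-$k$ partial correlation requires
  $n - 2 - k \ge 1$; violations are errors, not NaNs.
* Missing values are rejected on input by default (`na_policy = "reject"`);
  `"drop_variable"` removes affected variables with a warning. Partial
  correlation needs complete vectors and imputation is out of scope.
* Sample alignment keeps the transcript layer's sample order — an arbitrary
  but documented and deterministic tie-break. Replicate columns are kept as
  given; no averaging within conditions or time points is attempted.
* The pair table prints floats with 6 significant digits; `metabolite_1 <
  metabolite_2` lexicographically and rows sorted by pair, so outputs from
  identical runs are byte-identical.
* Output files from the command-line interface are written to a temporary
  file and renamed, so readers never observe partial writes.

## Problem sizes in the automated checks

The test suite exercises the pipeline at the generator's default scale
(300 transcripts, 30–32 metabolites, 60 samples) with 500 permutations per
fit and 5–10 independent datasets per property, and the unit tests use
smaller instances (tens of variables, 100–200 permutations). These sizes
were chosen so the full suite completes in a few minutes on a single core
while keeping every statistical check at a scale where its expected
behaviour is unambiguous; they are stated here so that readers know what
the reported properties were measured on.

## Known limitations

* The transcript PCs are an aggregate surrogate: a TPC call says the
  association runs through *dominant* transcriptional variation, not which
  genes carry it. Regulation through transcripts orthogonal to the first
  $p$ components is invisible to the method.
* The PPC difference condition is structurally conservative (see above).
* Pearson machinery assumes roughly elliptical dependence; strongly
  nonlinear or heavy-tailed couplings are outside the model.
* Permutation destroys any sample structure (time, batch, condition); for
  strongly structured designs the exchangeability assumption is only an
  approximation.
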