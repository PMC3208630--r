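---
title: "Methods: simultaneous differential-methylation testing with BCSVD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simultaneous differential-methylation testing with BCSVD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the model behind the BCSVD test, the parameters that matter and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical and design choices made where the method
left room.

## The problem and the model

The data are methylation array β values — per-CpG methylated fractions
β = M/(M+U) in [0, 1] — for a small case–control design: here, visceral
adipose tissue from prenatally androgenized (PA) female rhesus monkeys
versus controls, roughly a dozen samples against thousands of probes. A
probe-at-a-time analysis at this scale faces a brutal multiple-testing
burden; the BCSVD approach instead tests all probes **simultaneously in a
single model**.

Let $Z$ be the samples × probes matrix of per-probe standardized β values
(zero-variance probes are dropped and reported). The SVD $Z = U D V^\top$
compresses the probe space into at most $n-1$ sample-space scores
$S = U D$, without losing any information relevant to a linear
classification: for any probe-space coefficient vector in the row space of
$Z$, the likelihood of the model on $S$ equals that of the model on $Z$
(this identity is checked by a test to 1e-6).

Classification is a Bayesian probit with latent-variable data augmentation:

$$u_i \sim N(\mu + s_i^\top \gamma,\, 1), \qquad y_i = \mathbf{1}[u_i > 0],
\qquad \gamma \sim N(0, \tau^2 I), \quad \mu \sim N(0, 100).$$

All conditionals are conjugate, so the Gibbs sampler alternates a
truncated-normal draw of $u$ with a Gaussian draw of $(\mu, \gamma)$ whose
precision $X^\top X + P$ is fixed and Cholesky-factored once. The published
description of the method names Bayesian classification, SVD reduction, a
Gibbs sampler and permutation p-values but not the likelihood or prior;
this probit augmentation scheme is our reconstruction — chosen because it
is the canonical fully conjugate Gibbs formulation of Bayesian binary
classification — and is documented as such.

Probe-space effects are recovered through the loadings: $b = V\gamma$, and
the per-probe statistic is the **posterior mean of $b_j$**. Its sign gives
the direction: positive means hypermethylated in cases.

### Why the statistic is not divided by its posterior SD

A natural alternative statistic is mean$(b_j)$/sd$(b_j)$ per probe. We
implemented both and use the raw posterior mean, for a reason worth
recording: when the two classes are strongly separated (exactly the regime
the test should detect), the probit likelihood is flat in the magnitude of
$\gamma$ along the discriminant direction, so the posterior there is
limited by the prior ($\tau^2 = 100$) rather than the data — mean and SD
grow together and their ratio is nearly the same under the true labels as
under label permutations. In calibration runs at planted effect
Δβ = 0.3, SD = 0.05, the ratio statistic recovered under 10% of planted
loci while the raw posterior mean recovered over 90% with identical
permutations. The ratio variant remains available via
`probe_statistics(standardized = TRUE)`.

## Permutation empirical p-values

Labels are permuted $B$ times (default 99) and the **identical** fitting
procedure — same Gibbs iteration count, burn-in and prior — is re-run per
permutation; the standardization and SVD do not depend on labels and are
reused. Each probe's empirical p is per-probe with the add-one correction:

$$p_j = \frac{1 + \#\{b: |stat_{bj}| \ge |stat_j|\}}{B + 1} \ \ge\ \frac{1}{B+1}.$$

Three details matter:

* **Equal sampler settings under permutation.** Running shorter chains
  inside permutations (a tempting cost saving) breaks exchangeability: the
  Monte Carlo dispersion of the statistic depends on chain length and
  burn-in, and shorter-burn chains started at zero are systematically
  under-dispersed, which we measured as a type-I rate of ~0.22 instead of
  0.05. With equal settings the observed fit is exchangeable with the
  permuted fits by construction and calibration is restored.
* **Label canonicalization.** The augmentation model is exactly symmetric
  under label complement ($\theta \to -\theta$), so labels are recoded to
  make sample 1 a control before each fit and the statistic sign restored
  afterwards. Permutation p-values are therefore bit-identical under 0↔1
  relabeling of the input.
* **Discreteness.** With the add-one estimator p lives on the grid
  $k/(B+1)$; the event $p < 0.05$ has null probability
  $(\lceil 0.05(B+1)\rceil - 1)/(B+1)$, which is strictly below 0.05 for
  most $B$. Calibration checks therefore measure $P(p \le 0.05)$ at a $B$
  for which $0.05(B+1)$ is an integer (e.g. 19, 99); selection of
  significant probes keeps the conventional strict `p < alpha`.

Seeds: a master seed expands to per-permutation seeds by a fixed counter
scheme, so increasing $B$ extends the permutation set without changing
earlier permutations. When $B$ reaches the number of distinct label
assignments, those are enumerated exhaustively instead (subsets of the
minority class size, with a label-swap-invariant identification of the
observed assignment).

## Quality control

β values are recomputed as plain M/(M+U) (a configurable denominator
offset defaults to 0); negative background-corrected intensities are
clamped to zero; M+U = 0 yields a missing value. Probes are retained when
their detection p-value beats the threshold (default 0.01, strict) in at
least `min_sample_fraction` of samples (default all). Samples are screened
by PCA on probe-mean-imputed β values: the top 5 components are kept, a
sample is flagged as an outlier beyond 3 SD on any retained component (the
3-SD rule is this package's choice; the screening itself follows standard
array practice), and components are regressed against technical
covariates — ordinary least squares for continuous ones, a logistic (or
multinomial, for more than two levels) likelihood-ratio test for nominal
ones, with perfect separation reported as a flag rather than an error.

## Cross-species probe validity

Each 50-nt probe interrogates its CpG by single-base extension at the 3′
end. Against a different genome a probe is kept only if (1) its 3′-terminal
CG dinucleotide matches the genome exactly at both bases — we read the
published anchor criterion as a conjunction over both bases since extension
chemistry requires the terminal match; (2) it aligns with at most 3
substitutions of 50 (identity ≥ 94%); and (3) when several placements
exist, exactly one has 100% identity, and that one is taken (a unique hit
is judged by criteria 1–2 alone, the literal reading of "if multiple
matches were found"). Alignment is ungapped on both strands
(`Biostrings::matchPattern`; a brute-force sliding-window scan serves as
the independent oracle in the tests), with a default mismatch cap of 5 so
that criterion-2 failures at 4–5 mismatches are observed as hits rather
than silently vanishing. Probes are aligned as designed, without in-silico
bisulfite conversion, matching genomic alignment practice for this array.

Surviving probes must overlap the expected gene's body or its promoter
window. Coordinates are 0-based half-open internally (BED convention; GFF3
input is converted). The promoter window is strand-aware: $[TSS-1500, TSS)$
on the plus strand and $[TSS, TSS+1500)$ on the minus strand, where TSS is
`end - 1`.

## Validation and phenotype association

**LOOCV** refits standardize → SVD → probit on each leave-one-out training
set, standardizes the held-out sample with training means/SDs, projects it
onto the training loadings, and classifies at posterior predictive
probability 0.5 (ties toward control). The probe set is selected **once**
on the full data before LOOCV — replicating the published procedure — which
makes the estimate optimistic relative to nested re-selection; on the
strongly separated synthetic replica this distinction is immaterial (both
give 100%/100%), but it is the reason the LOOCV result should be read as
internal validation, not an unbiased error estimate.

**GLR power** follows the printed formula: power = 1 − Pr(χ²(1) ≥ −2 ln λ),
with λ the likelihood ratio of the intercept-only null (binomial MLE) to
the fitted model. The single degree of freedom is the published choice and
is implemented exactly as printed, although the alternative has more
parameters.

**Clustering** is agglomerative with Euclidean distance and average
linkage (the classic microarray-viewer defaults), deterministic given
input order.

**Phenotype rules** come from the published cutoffs: cycles longer than 34
days are intermittent/anovulatory; hyperandrogenism is testosterone ≥ 0.32
ng/ml (accepted as a literal override because the original threshold comes
from a larger external control set; a control mean + 1 SD derivation is
available); PCO is ≥ 10 follicles per greatest ovarian diameter.
Methylation–phenotype association is probe-wise ordinary least squares
within a mandatory sample subset (the study reports regressions within PA
animals, with the control subset run alongside as a negative control); raw,
Bonferroni and Benjamini–Hochberg columns are all reported because
published per-probe association p-values in this design (0.018–0.049)
cannot survive correction over hundreds of probes — the caller chooses.
Over-representation uses the exact hypergeometric right tail against a
caller-supplied reference list (e.g. the array's own gene list), with
`ratio = k / n_set`.

## The synthetic-data generator

The generator defines the study conditions for every test: 5 controls vs 7
cases (infant arm) or 5 vs 8 (adult arm); a 2,163-probe array (a
down-sampling of the 27,578-probe design, chosen so the full permutation
test runs in seconds); 163 or 325 planted differential loci at Δβ = 0.3
with within-group SD 0.05 — a strong but realistic array effect, consistent
with the published fully separable clustering and 100% LOOCV. Noise is
truncated normal on [0, 1] (the real β noise law is unpublished; this is a
stand-in, not a claim about the data). Batch effects are additive on the β
scale before truncation; batch labels are assigned round-robin. Intensities
are Poisson totals (mean 1000) split binomially by β, so recomputed β
values are unbiased; a configurable fraction of probes gets high detection
p-values to exercise filtering. The toy genome (2 × 50 kb, 20 genes)
carries seven planted probe classes that exhaust the validity verdicts,
planted on both strands, including engineered multi-mappers.

What the generator does **not** emulate: Infinium chemistry and dye bias,
bead-level replicates, bisulfite-conversion inefficiency, spatial artifacts,
correlated probes within CpG islands, and genome-scale alignment ambiguity.
Passing tests therefore demonstrate correctness of the statistical
machinery under the declared generative model, not robustness to every
artifact of real arrays.

## Numerical choices and problem sizes

* Gibbs defaults: 2,000 iterations, 500 burn-in, τ² = 100, intercept prior
  variance 100; identical inside permutations (see above).
* SVD rank: every singular value above 1e-10 is retained — reduction stops
  at the design-matrix rank, nothing smaller.
* Truncated-normal draws use inverse-CDF sampling with arguments clamped to
  [1e-12, 1 − 1e-12].
* Tie-breaking: permutation counts use ≥ (conservative); LOOCV probability
  ties go to control; `hclust` merges lowest indices first.
* Test-suite problem sizes: the full replica (2,163 probes, B = 99) runs
  once and is shared across checks; calibration uses 50 seeds × 100 probes
  at B = 19 with 800/200 chains; monotonicity uses 300 probes at three
  effect levels. These sizes keep the whole suite at roughly two minutes on
  one CPU while leaving every check at full strength.

## Known limitations

The probit likelihood/prior is a reconstruction of a method whose exact
form is not recoverable from its one-line published description; the LOOCV
optimism noted above; per-probe permutation p-values lose calibration *at
non-differential probes* when massive true signal is present elsewhere
(global shrinkage differences leak into every probe — the type-I guarantee
applies under the global null, which is what the calibration tests check);
and df = 1 in the power formula follows the source rather than counting
parameters.
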