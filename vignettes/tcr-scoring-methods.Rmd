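---
title: "Scoring T cell fate from the TCR sequence: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring T cell fate from the TCR sequence: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Each T cell carries an essentially unique alpha-beta T cell receptor (TCR)
created by V(D)J recombination before any fate decision is made. Because
recombination precedes differentiation, statistical associations between
receptor sequence and eventual transcriptional state — innate-like, CD8 vs
CD4, regulatory, memory vs naive — can be read causally. `tcrfate`
implements the quantitative machinery for that programme: it turns paired
alpha/beta amino-acid sequences into a fixed-length biophysical feature
vector, learns linear scoring functions that predict fate contrasts, and
provides the statistical tests that link scores to states across donors,
twins, and antigen-specific populations.

# Featurization

Six complementarity-determining loops are represented: CDR1 and CDR2 of
each chain (germline-encoded, recovered from the V-gene table) and the two
CDR3 junctions (taken from the contig record, with the invariant C and F/W
anchors dropped). Each loop is placed on a fixed number of residue slots —
7/8/15 for the alpha loops and 6/6/16 for the beta loops, 58 slots in all —
by *middle-out* gap alignment: the first `ceiling(L/2)` residues occupy the
leftmost slots and the rest the rightmost slots, so loop termini stay
anchored while insertions accumulate at the apex, mirroring IMGT-style
numbering. Shorter loops leave gap slots, which are tracked in a mask.

Four feature families are extracted per receptor:

* **Positional Atchley factors** — each occupied slot contributes the five
  published physicochemical factors of its residue (hydrophobicity,
  secondary-structure propensity, size, codon composition, charge/heat
  capacity): 5 × 58 = 290 features.
* **Composition** — the percentage of each loop occupied by 19 of the 20
  amino acids, glycine excluded as the reference (the 20 percentages are
  collinear; dropping one frees the model): 19 × 6 = 114 features.
  Denominators are true loop lengths, not slot counts.
* **Lengths** — one feature per loop, 6 in all.
* **Adjacent-residue interactions** — for each within-loop pair of adjacent
  slots, all 25 products of the two residues' factors. Interactions never
  cross loop boundaries (residues of different loops are not
  sequence-adjacent), and a pair is masked whenever either slot is a gap.

Features are standardized to mean 0, variance 1 over the *non-gap* entries
of the training set; gap entries are set to exactly 0 after scaling, i.e.
to the training mean. The scaling statistics are frozen into every trained
model, so that external data are always expressed in training-set units.
The registry (the ordered feature catalogue) is itself configurable and
hashed; scoring refuses feature matrices built under a different registry.

A note on accounting: the component counts above (290 + 114 + 6 + 25 per
adjacent pair) do not total 1,250 under any adjacency scope; the default
within-loop scope yields 52 pairs and 1,710 features. The registry is
therefore configuration-driven rather than hard-wired to one published
list; the 290/58/25-per-pair structure is the invariant the package pins.

The bundled V-gene table (`inst/extdata/vgene_table_synthetic.csv`) is
**synthetic** — fictional gene names with random CDR1/CDR2 sequences of
realistic lengths — sufficient for the simulator and the test suite. Real
analyses must supply a table translated from the IMGT reference.

# Quality control and clonotypes

The QC keeps cells with exactly one productive alpha and one productive
beta chain (dual-alpha/dual-beta cells are excluded), resolved V/J calls
with the V gene present and not flagged pseudogene, and CDR3 lengths of
10–17 (alpha) and 11–18 (beta) junction-inclusive amino acids. Rules are
applied in a fixed order — multiplet, unresolved genes, pseudogene, length
window — and each removed cell is attributed to the first failing rule, so
reports are reproducible. Clonotypes are keyed on the six components
(Va, Ja, Vb, Jb, CDR3a, CDR3b) at amino-acid level, with allele suffixes
stripped; expanded clones are reduced to one random representative cell
before any model fitting so that clone size cannot masquerade as signal.

# Twin concordance

A clonotype observed in exactly two donors is a "TCR twin" — the same
receptor arising independently in two immune systems. Each twin member is
assigned the transcriptional cluster containing the most of its cells
(ties broken toward the lexicographically smallest label, a documented
convention the underlying method leaves open). Under the null that states
are assigned without regard to sequence, the probability that a random
pair of twin-member cells shares a cluster is
`P_null = sum_j n_j (n_j - 1) / (N (N - 1))` over cluster sizes `n_j`, and
the observed number of concordant twins is tested against
`Binomial(n_pairs, P_null)` with an exact upper tail computed by log-gamma
summation in log space — the tail stays accurate far below 1e-30, which
matters because real cohorts produce vanishingly small p values.

# Learning scoring functions

**rCCA.** Axes of covariation between the TCR feature matrix and a
cell-state matrix (typically expression PCs, computed upstream) are found
by canonical correlation analysis with ridge-regularized covariances:
each view is whitened by `(Cov + lambda I)^(-1/2)` and the whitened
cross-covariance is decomposed by SVD. At `lambda = 0` this is classical
CCA (verified against an independent eigendecomposition); the penalties
are tuned by 5-fold cross-validation on the held-out first canonical
correlation. Significance comes from a permutation test that breaks the
row alignment between views; empirical p values are bounded below by
`1/(n_perm + 1)`. Signs are fixed so the dominant x-weight is positive,
with user-directed flips available because canonical directions are
sign-arbitrary.

**Ridge logistic scorers.** For a binary fate contrast the scoring
function is a ridge-penalized logistic regression on all features,
`logit P(state) = sum_j beta_j x_j + beta_0`, with the penalty chosen by
5-fold cross-validation minimizing held-out binomial deviance (the
conventional criterion; no class reweighting). Innate-like cells can be
excluded from fitting via `exclude` for contrasts where they are neither
class. The raw score is standardized by its training mean and sd, so one
score unit always means one training-set standard deviation, in any
dataset. Single-chain variants fit only one chain's features and are
provably invariant to the other chain's content — the tool for
nonproductive-rearrangement analyses, where only one chain is observed.
Loop-level attributions are computed by partition masking: zero one loop's
features, measure the mean absolute score change over cells of interest,
normalize shares to 1. This is a deliberate simplification of
Shapley-style attribution (single-group deletions rather than coalition
averages); for a linear model the group term is exact.

# Association and meta-analysis

Score-state association uses mixed-effects logistic regression with a
Gaussian donor random intercept, fitted by Laplace approximation
(`lme4::glmer`, `nAGQ = 1`); with one donor it reduces exactly to plain
logistic regression. Inference is Wald throughout, with a one-tailed
option for directional hypotheses in antigen-specific populations.
Per-donor effects (donors with ≥100 cells, ≥10 in each class) feed a
random-effects meta-analysis with maximum-likelihood heterogeneity
(`metafor::rma`, `method = "ML"`). Heterogeneity is summarized from
Cochran's Q as `I2 = max(0, (Q - df)/Q) * 100` and `H2 = Q/df` — the
Q-based forms, chosen deliberately over tau-squared-based versions so the
printed statistics are internally consistent with the reported Q. The
local false sign rate, the model-implied fraction of donors whose true
effect opposes the pooled sign, is the closed form `pnorm(-mu/tau)`.

# Dextramer background correction

Multiplexed pMHC-Dextramer UMI counts mix true binding with ambient
background driven by technical factors. For each non-control dextramer a
negative-binomial regression with log link models counts from the
negative-control dextramer counts, TCR expression (log CP10K of CDR3
UMIs), CLR-normalized CD3 and CD8 surface protein, and donor indicators
(reference-level dummy coding, first donor by lexicographic order).
Staining is then re-expressed as `Dnorm = log(observed/expected + 1)`:
zero counts map to 0, `observed = expected` maps to `log 2`, and the
transform is strictly increasing in the observed count. Binder calls are
thresholded per dextramer; thresholds are configuration (in practice set
by inspection of the bimodal `Dnorm` distribution), with
`find_antimode()` provided as an automatic convenience that deliberately
oversmooths (`adjust = 3`) so count discreteness near zero is not mistaken
for a mode. Within each antigen-specific population (≥10 distinct clones)
memory state is regressed on the TCR-mem score adjusting for `Dnorm` and
donor; effects are pooled across populations by the same ML random-effects
machinery.

# The synthetic cohort generator

Every analysis stage is testable without external data through a
generator with fully recorded ground truth:

* clone sizes are geometric (`1 + rgeom(p)`, default p = 0.6, mean ~1.7 —
  a modestly expanded blood-like repertoire), donors filled to an exact
  cell budget;
* CDR3 junctions are uniform random interiors with C/F anchors, lengths
  drawn inside the QC windows so generated data pass QC with zero
  removals (a tested invariant);
* a configurable fraction of clonotypes is copied verbatim into a second
  donor, giving planted TCR twins; the twin cohort variant draws
  cluster labels per clone and can force twin concordance with
  probability delta to exercise the power of the concordance test;
* binary states follow `Bernoulli(plogis(w . x + b + u_donor))` with a
  sparse planted weight vector (default: 10 features at 0.5 sd, random
  signs, donor intercept sd 0.5);
* Dextramer counts follow the background model's own covariate structure
  with planted binder cells spiked 20-fold; the background dispersion
  default (`theta = 5`) was set so the generator meets its contract —
  spike 1 is undetectable (AUC ~ 0.5) and spike 20 is clearly bimodal
  (AUC > 0.99).

Two generator design points deserve emphasis. First, planted effect
features are drawn from CDR3 positional features on slots occupied at
every admissible junction length. Slots without gaps realize the
configured effect size exactly, and — more fundamentally — junction
residues vary cell by cell, whereas germline CDR1/CDR2 features are
deterministic functions of the finite V-gene vocabulary and hence
collinear at the gene level: a sparse "true" weight placed there is not
identifiable by any estimator, so recovery checks would be meaningless.
Second, the five Atchley factors are mutually correlated across the 20
residues (factors 3 and 5 correlate at 0.83 in the published table), so a
true feature's same-slot factor partners legitimately carry shrunken
weight in ridge fits; recovery checks should expect partners near, not
above, true features.

What the simulation does *not* emulate: V(D)J generation biases and
nucleotide-level convergence, position-specific amino-acid preferences
(a hook for a frequency table exists), thymic selection, HLA structure,
antigen-driven clonal covariance between donors, and transcriptional
measurement noise. Passing tests therefore demonstrate correctness of the
estimators under the package's own generative assumptions, not biological
validity on real repertoires.

# Numerical and problem-size choices

* The binomial tail is summed in log space from the largest term
  (log-sum-exp over log-gamma coefficients); agreement with the
  incomplete-beta algorithm in `pbinom` is tested to 3 significant digits
  down past 1e-30.
* The rCCA whitening floors eigenvalues at machine precision relative to
  the largest, so rank-deficient views degrade gracefully.
* Zero-variance features scale to 0 rather than NaN; all-gap columns are
  zero by the same rule.
* Mixed-model convergence warnings are captured and surfaced as a
  `converged` flag, never silently dropped; the same applies to the NB
  background fits.
* Test and verification problem sizes — e.g. 20,000-cell repertoires for
  full-scale recovery, 200 replicates for calibration checks, 1e6 draws
  per Monte-Carlo oracle comparison, 20 seeds for the end-to-end chain —
  were chosen as the smallest sizes at which the expected effects are
  resolvable with comfortable statistical margins.

# Limitations

The scoring functions are linear; motif or epistatic effects beyond
adjacent-residue products are out of scope, as are gamma-delta receptors,
dual-chain cells, nucleotide-level clonotyping, and any upstream
processing (alignment, clustering, batch correction, reference mapping) —
cluster labels and expression PCs are consumed as given. Shipped gene
content is synthetic; real analyses require an IMGT-derived V-gene table.
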