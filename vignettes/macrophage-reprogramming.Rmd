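---
title: "Modelling macrophage polarization: gene-set filtering, flux prediction and in-silico reprogramming"
author: "macrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling macrophage polarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macrep)
```

# Scope

Macrophages polarize into a classically activated, pro-inflammatory state
(M1, induced by LPS + IFN-γ) or an alternatively activated,
immunosuppressive state (M2, induced by IL-4), with distinct metabolic and
regulatory programs. `macrep` implements three computational procedures for
studying this switch and reversing it in silico:

1. **Gene-set redundancy filtering** — reduce a list of enriched gene sets
   to a non-redundant subset by maximum-weight stable-set selection on a
   Jaccard similarity graph.
2. **Expression-constrained flux prediction** — fit per-phenotype metabolic
   fluxes whose magnitudes track enzyme expression, subject to steady-state
   stoichiometry, and iteratively remove thermodynamically infeasible loops.
3. **Regulatory-network inference and reprogramming** — select a small,
   shared set of transcription factors (TFs) whose activities explain a gene
   signature through a mixed-integer L1 regression, then predict the
   signature's expression after swapping selected TF activities between
   phenotypes.

All optimization problems are expressed through one solver-agnostic
container (`lmp()`); linear and mixed-integer programs are solved through
the bundled GLPK interface, and the regression selection problem
additionally has a specialized exact solver (below). Seeded generators
(`generate_expression()`, `generate_toy_network()`, `generate_gene_sets()`)
produce inputs with the statistical structure the analysis assumes, so the
entire pipeline is testable without external data.

# Gene-set filtering

Redundancy between gene sets $A$ and $B$ is the Jaccard coefficient
$J(A,B) = |A \cap B| / |A \cup B|$. Sets are vertices of an undirected graph
with an edge wherever $J \ge 0.5$ (configurable); each vertex carries weight
$w_i = 1 - \log_{10}(p_i)/100$ from its enrichment p-value, so all weights
are close to 1 and the selection primarily maximizes the *number* of
retained sets, with significance breaking ties. The filter solves the
maximum-weight stable set problem

$$\max \sum_i w_i x_i \quad \text{s.t.} \quad x_i + x_j \le 1 \;\;
\forall \{i,j\} \in E, \; x_i \in \{0,1\},$$

exactly, by branch-and-cut. Among multiple optima the deterministic
tie-break of the backend (fixed variable order, no randomization) is
accepted, so repeated runs return the same selection.

# Flux prediction

The metabolic network is a stoichiometric matrix $S$ with reaction bounds
$lb_r \le v_r \le ub_r$, flat gene associations (Boolean gene-protein-
reaction logic is deliberately flattened to a gene list), and a biomass
reaction with a production floor (default $0.028$, the maintenance growth
rate of the murine macrophage reconstruction this models). Flux variability
analysis (`run_fva()`) computes each reaction's attainable signed flux range
under $Sv = 0$, the bounds and the biomass floor, and from it the absolute
range $[\mathrm{minV}_r, \mathrm{maxV}_r]$ ($\mathrm{minV}_r = 0$ whenever
the signed range spans zero).

A reaction's expected flux magnitude follows its genes' expression linearly
(`expression_to_flux_magnitude()`):

$$|\tilde v_{r,p}| = \mathrm{minV}_r + (\bar g_{r,p} - \mathrm{minG}_r)\,
\frac{\mathrm{maxV}_r - \mathrm{minV}_r}{\mathrm{maxG}_r - \mathrm{minG}_r},$$

where $\bar g_{r,p}$ is the phenotype-mean z-score of an associated gene and
$\mathrm{minG}_r, \mathrm{maxG}_r$ are the extremes for the reaction across
all phenotypes and genes (computed across *all* conditions, not only a
compared pair; this is configurable by subsetting the expression matrix).
The implementation evaluates the interpolation in convex-combination form,
which is exact at both endpoints in floating point. Reactions without gene
association, blocked reactions and reactions with constant expression
(degenerate $\mathrm{maxG} = \mathrm{minG}$) are excluded from the
objective — exclusion being the least-assumption treatment of an undefined
interpolation.

`fit_fluxes()` minimizes the weighted L1 deviation
$\sum w_{r,p} \,\big|\, |v_r| - |\tilde v_{r,p}| \,\big|$ with one term per
(reaction, gene, phenotype). Core reactions — those of the pathways under
study (glycolysis, citrate cycle, urea cycle, IMP synthesis in the original
setting) — carry weight $100/(\mathrm{maxV}_r\, n)$, their direct neighbors
$1/(\mathrm{maxV}_r\, n)$, with $n$ the reaction's gene count; the
$100{:}1$ ratio concentrates the fit on the pathways of interest while the
$1/\mathrm{maxV}$ factor normalizes for flux scale. "Direct neighbor" means
sharing at least one non-currency metabolite with a core reaction; common
cofactors (H+, H2O, ATP, ADP, Pi, NAD(H), NADP(H)) are excluded from the
neighborhood definition by default because they would make nearly every
reaction a neighbor. Absolute values are linearized by splitting
$v = v^+ - v^-$ with a binary direction indicator per reversible reaction,
so $|v| = v^+ + v^-$ exactly; the sign of $v$ is never fixed by the targets,
only its magnitude, so reversible reactions choose direction freely subject
to stoichiometry.

## Loop removal

A thermodynamically infeasible loop is a set of internal reactions carrying
flux around a stoichiometrically balanced cycle with no exchange
involvement. After each fit, the support (internal reactions with
$|v_r| \ge 0.01$; the threshold balances run time against resolution, and
exchange reactions cannot participate in such loops so they are excluded)
is oriented along the current flux directions and the minimum-cycle MIP

$$\min \sum_r \lambda_r \;\; \text{s.t.} \;\;
\sum_r S_r \lambda_r = 0,\;\; \lambda_r \ge \mathrm{inFC}_r,\;\;
\lambda_r \le M\,\mathrm{inFC}_r,\;\; \sum_r \mathrm{inFC}_r \ge 2$$

is solved over the support. The coupling $\lambda \le M\,\mathrm{inFC}$
(with $M = 1000$, above any shipped bound) is required for the binary
indicator to be 1 *only if* the reaction carries cycle flux. If the MIP is
infeasible there is no loop and fitting stops; otherwise the detected cycle
$\{r_1,\dots,r_k\}$ is forbidden in the main problem through one binary
relief variable $a_r$ per member:

$$v^{\pm}_{r} \le (0.01 - \varepsilon) + M a_r, \qquad \sum a_r \le k - 1,$$

which forces at least one member's directional flux strictly below the
support threshold after the re-fit (the $\varepsilon = 10\times$ solver
tolerance guards against the boundary case in which a flux exactly at the
threshold would re-enter the support and the same cycle would be detected
forever). Detection prefers minimal cycles first, which keeps the number of
cuts small. Because cuts only constrain cycle members, the
exchange-to-biomass throughput of the solution is unaffected by loop
removal on networks whose cycles are not load-bearing — a property the test
suite verifies on generated networks with planted 2-, 3- and 4-cycles.

Differential flux between phenotypes is reported on a 0–100% scale:
0 when the absolute fluxes agree, 100 when flux is present in exactly one
condition, otherwise $\big||v_1|-|v_2|\big| / \max(|v_1|,|v_2|) \times 100$.

# Regulatory model

## Evidence and activities

TF→target records from six source tiers are aggregated into an edge score:
curated direct interactions contribute 2; the three medium-confidence
sources (curated-unspecified, ChIP enrichment, conserved binding sites)
contribute 1 *each*, but only for pairs present in at least two of those
three sources (a pair in exactly one of them receives nothing from that
tier — the least-generous reading of an underspecified rule); mouse ENCODE
contributes 0.5 and text-mining/expression-inference evidence 0.25. A pair
is "known" when its score is positive. Only TFs with at least 15 known
targets inside the signature are eligible. The activity of a TF in a sample
is the mean z-score of its known targets present in the matrix.

## Selection regression

For target genes $i$ and samples $k$, the model

$$\tilde g_{i,k} = \beta_{0,i} + \sum_t \beta_{t,i}\,
\mathrm{ES}_{t,i}\, \mathrm{act}_{t,k}$$

is fitted by minimizing $\sum_{i,k} |g_{i,k} - \tilde g_{i,k}|$ with one
binary selection variable per TF shared across all targets, at most 5
selected (the regulator cap), and $\beta_{t,i}$ free only for selected TFs
with a known interaction. The printed form of this objective in the source
method matches magnitudes ($\big||g| - |\tilde g|\big|$), which discards
the sign of z-scores; the package default is the plain L1 objective, with
the magnitude-matching variant available via `objective = "magnitude"`.

Two exact solvers are provided. The generic path encodes the problem as a
big-M MIP ($|\beta| \le 100\, y_t$; 100 is generous for z-scored data) and
hands it to GLPK. The default path exploits the structure: once the TF
subset is fixed the problem separates into tiny per-gene L1 regressions,
each solvable exactly by enumerating interpolation vertices (an optimal L1
fit with $p$ parameters and full-rank design passes through $p$ points);
per-gene values are memoized over the gene's local regulator subset and the
outer problem is solved by exhaustive enumeration of all TF subsets up to
the cap. Both routes optimize the identical objective — a unit test checks
their agreement — but the decomposition is orders of magnitude faster at
study scale (tens of milliseconds instead of tens of seconds per fit),
which is what makes the bootstrap below tractable with an open-source
stack. Ties between optimal subsets are broken deterministically toward
smaller, lexicographically earlier subsets.

Cross-validation assigns samples to 3 folds by seeded shuffling; each fold
is held out once and the held-out mean absolute error and per-fold selected
TF set are recorded; reported coefficients come from a refit on all samples
(refit-on-all after CV-based assessment is the conventional resolution of
how fold models combine into one reported model).

## Bootstrap and parsimony

`bootstrap_selection()` repeats (default 1000×): sample 10 signature genes
without replacement, fit the selection regression within the 3-fold
cross-validation, and record each training fold's selected TFs. Each TF's
selection count over the $reps \times folds$ draws is tested against the
uniform-choice null — every cap-sized subset of the $T$ eligible TFs
equally likely, i.e. expected count $N \cdot \mathrm{cap}/T$ — with a
one-sided Fisher's exact test (the test equals the exact hypergeometric
tail, which the test suite verifies independently), followed by
Benjamini–Hochberg adjustment. The nine top-ranking TFs (smallest adjusted
p-values; ties by count, then name) are carried forward.

`fit_parsimony_model()` restricts the candidates to those TFs and fits the
full signature. The regulator cardinality is chosen by cross-validation
with the **one-standard-error rule**: the smallest cap whose CV error is
within one SE of the best. A fixed-cap fit alone cannot yield a parsimonious
model — with noisy data the MIP always uses the full cap because an extra
regressor never hurts the training objective — so an explicit
cardinality-selection rule is required, and the 1-SE rule is the standard
one for CV-based model choice.

## Reprogramming

`reprogram()` keeps all coefficients of the source-phenotype model and
replaces the activities of a chosen TF subset with the target phenotype's
activities (phenotype-level activity = mean over that phenotype's samples):

$$\tilde g_{i,\,src \to tgt} = \beta_{0,i}
 + \sum_{t \in \mathrm{subset}} \beta_{t,i} \mathrm{ES}_{t,i}\,
   \mathrm{act}_{t,tgt}
 + \sum_{u \notin \mathrm{subset}} \beta_{u,i} \mathrm{ES}_{u,i}\,
   \mathrm{act}_{u,src}.$$

A gene counts as **switched** when its reprogrammed prediction lies closer
to the observed target-phenotype mean than to the observed source-phenotype
mean — a symmetric, scale-free operationalization of "switched its
expression state". `evaluate_subsets()` tabulates the switched fraction for
every non-empty subset of the selected regulators.
`compare_to_signature()` scores predicted reprogramming directions against
an externally supplied signed differential-expression table.

# Synthetic data

`generate_expression()` emulates a three-phenotype (M0/M1/M2) design with 3
biological × 2 technical replicates. Latent TF activities have a phenotype
mean (drawn N(0,1) per TF and phenotype, so phenotypes genuinely differ —
required for reprogramming to be meaningful) plus biological-replicate
jitter (sd 0.15); technical replicates share their biological replicate's
activity and differ only through the observation noise (sd 0.2 by default).
Expression is the linear model above evaluated at the generated edge scores
plus Gaussian noise. Planted effect sizes are $|\beta| \in [0.5, 2]$ and
**predominantly activating** (80% positive): with sign-balanced regulons
the target-averaging activity estimate cancels toward zero for the very TFs
that drive the data, which would make the estimator — and hence recovery —
uninformative by construction; most signature regulators in this domain
(E2F1, MYC) indeed act as net activators. Each gene is driven by **exactly
one** true TF (balanced assignment, 28 targets per TF at the default
112-gene/4-TF setting): disjoint regulons make the activity estimator a
consistent, scaled readout of each latent activity, so the 4-regulator
model class is well-specified. With overlapping regulons the estimates
become TF mixtures and an additional decoy regressor genuinely improves
held-out prediction, which no honest parsimony rule would then reject.
Decoy TFs receive 15–40 evidence-supported targets uniformly at random
(passing the eligibility filter) but do not influence expression; evidence
tiers are drawn across all six sources.

What the generator deliberately does **not** emulate: count-level RNA-seq
noise (values are Gaussian on the z-scale), overlapping and antagonistic
regulons, TF–TF interactions, and any coupling between the regulatory and
metabolic layers. Passing recovery tests therefore demonstrate correctness
of the inference machinery under its own assumptions, not performance on
real transcriptomes.

`generate_toy_network()` builds a linear pathway (input exchange → A → B →
C with a biomass drain and an output branch) plus a planted
stoichiometrically balanced internal cycle of length 2–4 attached at B, and
returns a generating flux vector that satisfies the steady state, the
bounds and the biomass floor while carrying the cycle.
`generate_gene_sets()` produces collections whose consecutive pairs
straddle the 0.5 Jaccard threshold, with p-values log-uniform on
$[10^{-30}, 0.05]$. All generators are pure functions of their seed.

# Numerical choices and problem sizes

* Solver feasibility/integrality tolerance: $10^{-6}$; z-scores use the
  sample standard deviation (divisor $n-1$); constant genes map to all-zero
  z-rows rather than being dropped, keeping dimensions stable.
* Technical replicates are averaged into one column per biological
  replicate before z-transformation by default (they are not independent
  observations); downstream stages therefore see 9 samples in the default
  design, which also keeps the 3-fold cross-validation folds balanced.
* The test suite runs the gene-set filter against an exhaustive independent-
  set oracle on 100 collections of up to 20 sets; loop removal on 30
  planted-cycle networks; and regulator recovery at the full study scale
  (112 genes, 4 true + 26 decoy TFs) with 200 bootstrap repetitions on each
  of 10 seeds — about two minutes of solver time in total, which is the
  package's chosen compromise between statistical resolution and a test
  suite that runs on every check.

# Limitations

* The enumeration solver requires the signed-L1 objective, at most ~24
  samples and a tractable number of TF subsets; outside that envelope the
  generic big-M MIP path is used, which is exact but markedly slower.
* FVA and the flux fit solve one LP/MIP per reaction or per phenotype; the
  implementation targets pathway-scale and toy networks, not
  genome-scale reconstructions with tens of thousands of reactions.
* The Fisher null treats bootstrap draws as independent cap-sized uniform
  selections; correlations between folds of the same repetition are
  ignored, exactly as in the original prioritization scheme.
* In-silico reprogramming inherits the linearity of the regression model:
  it cannot express saturation, cooperativity or indirect cascades.
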