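---
title: "Methods: collective tri-factorization for paired drug-disease tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collective tri-factorization for paired drug-disease tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofactR)
```

## The problem and the model

Drug–disease association catalogs distinguish *therapeutic* links (the drug
treats the disease) from *marker/mechanism* links (the drug correlates with
or contributes to the disease). The two link types are mutually exclusive in
practice — a cell of the drug × disease grid carries at most one — and the
two prediction problems share their entities. cofactR models them as two
coupled matrix-completion tasks.

Each binary matrix is approximated by a tri-factorization `A ≈ U R Vᵀ`: `U`
(m × k) holds drug representations, `V` (n × k) disease representations, and
the k × k coefficient matrix `R` captures how latent drug and disease
components interact *for that link type*. `U` and `V` are shared between the
two tasks — that sharing is the multi-task coupling — while `R^p` and `R^n`
stay task-specific. Two further penalties encode prior structure:

* **Graph Laplacian terms** `(α/2)·tr(Uᵀ L^U U)` and `(β/2)·tr(Vᵀ L^V V)`
  pull the latent rows of similar drugs (diseases) together, since
  `tr(Uᵀ L U) = ½ Σᵢⱼ ‖U(i,:) − U(j,:)‖² wᵢⱼ`. The Laplacians come from a
  Tanimoto similarity on binary drug feature profiles and a semantic
  similarity on disease MeSH hierarchies.
* **L2 (ridge) terms** on all four factor matrices, weighted λ/2.

The model's central assumption is that one shared low-dimensional embedding
explains both link types, with the task differences concentrated in the
small coefficient matrices. When that assumption is false (tasks with
unrelated structure), the coupling can hurt; the single-task mode
(`mode = "single_task_p"` / `"single_task_n"`) exists exactly to measure
that by ablation, with identical machinery and parameters.

## Similarities

**Drugs.** A drug's profile is a set of binary descriptors (e.g. chemical
substructures). Similarity is the Jaccard/Tanimoto index
`|Γᵢ∩Γⱼ| / (|Γᵢ|+|Γⱼ|−|Γᵢ∩Γⱼ|)`; the implementation computes it by set
counting and the tests pin it against the equivalent inner-product form on
binary encodings. A drug with an empty profile gets similarity 0 to
everything *including itself* (logged as a warning): aborting would make a
whole dataset unusable because one drug lacks annotation, and a zero row
simply removes that drug from the Laplacian coupling.

**Diseases.** Each disease's MeSH tree numbers are expanded into the DAG of
all dot-prefixes (`C04.557.337` contributes `C04`, `C04.557`,
`C04.557.337`); node identity is the tree-number string, so shared ancestry
is shared prefix. The semantic contribution of the disease's own node(s) is
1 and decays by a factor Δ per level upward, taking the maximum over
children; the disease's semantic value is the sum of contributions, and the
similarity of two diseases is the contribution mass on shared nodes divided
by the sum of their semantic values. Δ defaults to 0.5, the standard choice
in this similarity lineage.

Two conventions were genuinely open and are decided here:

* A disease with several tree numbers gets **one merged DAG** with all full
  tree numbers as own nodes (contribution 1 each). The alternative —
  separate DAGs per tree number combined afterwards — is not what the
  similarity definition operates on, and the merged form keeps
  self-similarity exactly 1.
* Diseases with no MeSH annotation get similarity 0 everywhere rather than
  raising an error, mirroring the empty-profile convention for drugs.

## Optimization

The Laplacian terms are decoupled from the reconstruction terms by auxiliary
copies `W = U`, `J = V`, giving an equality-constrained problem solved by
ADMM on the augmented Lagrangian (multipliers `Z`, `Y`; penalties ρ₁, ρ₂).
Per iteration:

1. `R^p`, `R^n` from the ridge normal equation
   `(UᵀU) R (VᵀV) + λR = Uᵀ A V`, solved by **matrix-free conjugate
   gradients** on the k²-dimensional operator (never forming the k² × k²
   Kronecker matrix), warm-started from the previous iterate.
2. Closed-form primal updates for `J`, `W`, `U`, `V` in that order. Each is
   the exact stationary point of the augmented Lagrangian in its block:
   `J` and `W` solve SPD Laplacian systems (Cholesky), `U` and `V` solve
   k × k SPD systems on the right. `J` uses the pre-update `V`; `U` uses the
   fresh `W`. One sweep per ADMM iteration — the update rule lists one pass,
   and multiple inner sweeps would only re-solve against unchanged
   multipliers.
3. Dual ascent `Y += ρ₂(J−V)`, `Z += ρ₁(W−U)` and geometric penalty growth
   `ρ ← min(μρ, ρ_cap)` with μ = 1.1.

Numerical choices worth stating:

* **Initialization** of `U`, `V` is uniform in [0, 1] under the configured
  seed; the updates themselves are unconstrained (no nonnegativity is
  imposed — the closed forms, not the initialization range, define the
  iteration).
* **Penalty cap** `ρ_cap = 1e6`. Uncapped geometric growth eventually makes
  the primal systems ill-conditioned and freezes `J`, `W` onto `V`, `U`
  before the factors settle; capping at 1e6 is standard ADMM practice.
  `rho_cap = Inf` restores the uncapped schedule.
* **Convergence** is declared when both relative primal residuals
  `‖J−V‖/max(1,‖V‖)` and `‖W−U‖/max(1,‖U‖)` drop below `tol = 1e-4`, or the
  relative objective change stays below 1e-6 for 5 consecutive iterations,
  or at `max_iter = 500`.
* **Inner CG tolerance** is 1e-10 relative residual (cap 200 iterations).
  A looser 1e-8 residual leaves solution error up to the system's condition
  number, which is visible when the solve is compared against a dense
  oracle; at k ≤ 40 the tighter tolerance costs microseconds.
* A **NaN/Inf guard** runs every 10 iterations and aborts with a diagnostic
  rather than returning garbage.
* Degenerate inputs: `k ≥ min(m, n)` and a missing seed are rejected up
  front; an all-zero coefficient right-hand side short-circuits CG to the
  zero matrix (which is also what makes the single-task and two-task fits
  coincide exactly when the other matrix is all zero).

Default hyperparameters (`k = 30`, `α = β = 8`, `λ = 4`) follow the
grid-search optimum reported for the therapeutic task on the reference
benchmark; for synthetic harnesses with planted rank ~5 the tests use
`k = k_true`, `α = β = λ = 1`.

## Evaluation protocol

Positives of each task are split into 5 near-equal folds independently and
uniformly at random. For each fold, **both tasks' fold positives are masked
in the same fitted model**: a joint model fitted with one task's test links
still present would leak them into the shared factors.

Per task, the evaluation universe is every cell that is not a *training*
positive of that task. Cells positive in the *other* task count as negatives
by default — under mutual exclusivity they are known non-members of the
scored task. Because the original protocol does not pin this convention
down, `exclude_cross_type = TRUE` reproduces the other choice.

* **Threshold metrics** sweep every distinct score as a candidate threshold
  (positive iff score ≥ threshold) and report SE, SP, PRE, ACC, F at the
  F-maximizing threshold; F ties break toward the higher threshold (fewer
  predicted positives). The sweep is epsilon-robust to 1-ulp float
  differences between algebraically equal F values.
* **AUC** is the tie-corrected Mann–Whitney rank statistic; **AUPR** is the
  step-wise precision-recall integral (average precision over positive
  ranks), with score ties broken deterministically by cell index. Both are
  pinned against exhaustive pairwise / rank-enumeration oracles in the
  tests.
* **Top-N curves** report recall and precision of the N best-scoring cells
  for N on a 10..1000 grid (capped at the universe size).

## The synthetic generator

`generate_synthetic()` emulates the *structure the model assumes*: planted
nonnegative factors `U*`, `V*` (uniform [0, 1]) shared by both tasks,
distinct coefficient matrices, mutual exclusivity, and similarity matrices
derived from the same planted factors (row-cosine similarity plus a clipped
symmetric Gaussian perturbation, unit diagonal) so that the Laplacian terms
are informative. Cells are assigned to the type with the higher
*standardized* score — the overall scale of a random coefficient matrix is
arbitrary, and comparing raw scores would let whichever `R*` drew the larger
mean claim nearly every cell — and a cell becomes a positive iff its score
ranks above the per-type quantile realizing the target density. Label noise
drops each positive with probability `noise` and promotes a matched count of
all-zero cells in the same task, keeping densities stable and exclusivity
intact.

Defaults mirror the reference benchmark's shape: 269 drugs × 598 diseases
with densities 0.0388 / 0.0757 (≈6,244 therapeutic and ≈12,172
non-therapeutic positives), `noise = 0.05` as a realistic curation error
rate, and `sim_noise = 0.1` so similarities are informative but not clean.
The scaled-down acceptance harness uses 150 × 200 with `k_true = 5`.

What a green test does **not** establish: real association data are not
generated by a low-rank bilinear form, real similarity matrices are not
noisy functions of the same factors that generate the links (the generator's
construction makes the Laplacian prior *correct*, which flatters it), drug
feature sparsity and MeSH annotation depth are not modeled, and the degree
distributions of real networks are heavier-tailed. The synthetic results
validate the optimizer, the protocol and the multi-task mechanics — not
benchmark-level performance claims.

## Known limitations

* The two fitted score matrices are not calibrated against each other; a
  cell can rank high for both types in the merged prediction list, exactly
  the conflict the joint model reduces but does not forbid.
* One similarity source per entity type; integrating several drug feature
  spaces is out of scope.
* Dense linear algebra throughout: fine for the 10²–10³ entity scale this
  targets (a full 269 × 598, k = 30 fit takes seconds), not for 10⁵-entity
  catalogs.
* The conflict policy for dual-annotated pairs ("therapeutic wins" by
  default, `drop` and `non_therapeutic` selectable) is a data-cleaning
  choice made before modeling; nothing downstream revisits it.
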