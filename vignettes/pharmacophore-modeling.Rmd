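---
title: "Quantitative pharmacophore modeling and screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative pharmacophore modeling and screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

A pharmacophore hypothesis is a set of at most five typed feature spheres
in 3D space — hydrogen-bond donors (HBD) and acceptors (HBA), hydrophobes
(HBic) and aromatic rings (RingArom) — each with a center, a tolerance
radius (default 1.6 Å) and a non-negative weight (default 1). A molecule
matches the hypothesis when some conformer presents feature points that can
be brought, by one rigid motion, inside the tolerance spheres of a
kind-compatible, injective assignment of hypothesis features to points.
The quality of a match is the fit value

fit = Σ_mapped w_f · max(0, 1 − (d_f / tol_f)²),

where d_f is the post-alignment displacement of feature f from its matched
point. The fit is bounded by the total feature weight, reached exactly when
every displacement vanishes, and decreases monotonically as displacements
grow. Proprietary fit formulas in commercial packages are not published;
this definition keeps their qualitative contract (distance deviation from
feature centers; higher is better; bounded by feature count × weight).

A *quantitative* (HypoGen-style) hypothesis additionally carries a linear
calibration from fit value to activity, pIC50 ≈ slope · fit + intercept,
estimated by least squares over a training set, and a cost report in bits
(below).

## Mapping engine

`map_conformer()` searches all kind-compatible injective correspondences,
pruned by pairwise-distance compatibility
(|d_model(i,j) − d_points(i,j)| ≤ tol_i + tol_j), aligns each candidate by
weighted Kabsch superposition (proper rotations only; mirror images are
never accepted), enforces the hard tolerance constraint on every mapped
feature, and returns the feasible correspondence with maximal fit. Ties are
broken deterministically: lower weighted RMSD, then lexicographically
smallest correspondence. A branch-and-bound rule makes this exact search
fast: the weighted SSD of any partial assignment under its own optimal
superposition lower-bounds the SSD of every completion, which both caps the
attainable fit (pruning against the best solution found so far) and
certifies infeasibility. The bound uses closed-form singular values of the
3×3 weighted covariance, so interior nodes cost a few dozen floating-point
operations.

The Kabsch solve minimises weighted RMSD, which is fit-optimal only when
all tolerances are equal; it can also reject a correspondence that a
different rigid transform would make feasible. The `"best"` search mode
therefore re-optimises the winning (and the best near-miss) alignment
directly on the penalised fit objective with Nelder–Mead, mirroring a
best/flexible database search; `"fast"` mode scores stored conformers with
the Kabsch alignment only.

## Omitted features

Database screening uses a maximum-omitted-features allowance of zero: a hit
must satisfy every feature of the query. Activity *estimation* instead
allows one omitted feature, so weakly active molecules that present most of
the arrangement receive graded low fits rather than an all-or-nothing
score; molecules mapping fewer features contribute fit 0 (and are predicted
at the calibration intercept). Dropping unmapped molecules from the
regression was rejected because it biases the line toward actives. The
allowance of one is a compromise between gradation (weak training
compounds commonly map only a subset of a five-feature model) and
specificity — each additional allowed omission makes spurious partial
matches against unrelated feature points markedly more likely and the
correspondence search combinatorially larger.

# Hypothesis generation

`build_hypotheses()` follows the constructive/subtractive/optimisation
scheme of quantitative pharmacophore generation:

1. **Partition.** Relative to the most potent training molecule, *leads*
   lie within uncertainty² (default 9×) of the minimum IC50, *inactives*
   at least 10^3.5-fold above it (boundary inclusive), the rest are
   moderates. The multiplicative uncertainty (default 3) means a measured
   activity is trusted only to within a factor of three either way.
2. **Constructive phase.** Feature subsets (size 3–5 by default, hard cap
   5) of the most active lead are retained as candidates when the other
   leads map them fully. Two robustness choices: at most the 12 most
   active leads drive this phase, and one lead is allowed to miss a
   candidate — with experimental noise of ~0.3 log units, a borderline
   molecule occasionally enters the lead set while genuinely lacking a
   feature, and without the allowance a single such outlier vetoes every
   complete candidate. A subset-monotonicity argument (a lead failing a
   3-subset fails every superset) lets cheap triple checks prune the
   enumeration. Candidates are deduplicated by kind multiset plus a
   rounded pairwise-distance signature.
3. **Subtractive phase.** Candidates fully mapped by more than half of the
   inactive molecules carry no discriminating information and are removed
   (strictly more than half: mapping exactly half is retained).
4. **Cost ranking and annealing.** Candidates are ranked by total cost; the
   best few (default 5) are refined by simulated annealing over feature
   centers (Gaussian steps, σ = 0.5 Å), tolerances (log-normal steps,
   clamped to 1–2.5 Å) and weights (clamped to 0.1–3). The start
   temperature is set so that roughly half of early uphill proposals are
   accepted, followed by geometric cooling (0.97 per step, 80 steps by
   default). The procedure is fully seeded and keeps the best-so-far, so
   the returned ranking is deterministic and never worse than the best
   unoptimised candidate. When more than 30 candidates survive, a cheaper
   pre-ranking (one omitted feature allowed in scoring) selects the
   shortlist that receives the full evaluation. At most ten hypotheses are
   returned, sorted by total cost.

Feature-kind swap moves exist as an optional annealing move but are
disabled by default; with them enabled the feature multiset of a candidate
is no longer stable under optimisation, which is occasionally useful for
exploring near-degenerate topologies.

## The cost model

Costs are reported in bits:

* **error cost** = k_e · Σ_i max(0, |pIC50_i − est_i| − log10(u))², i.e.
  residuals inside the ×u uncertainty band (u = 3 by default) cost
  nothing. k_e = 1/(2 ln 2 σ²) with σ = 0.3 log units, so a residual one
  reference-noise unit beyond the band costs 1/(2 ln 2) bits.
* **weight cost** = k_w · Σ_f (w_f − 1)², k_w = 1 bit per squared unit of
  deviation from unit weight.
* **configuration cost** = log2(number of candidate configurations
  explored).
* **total cost** = error + weight + configuration, exactly.
* **null cost** = error cost of the constant mean-activity predictor;
  **fixed cost** = the floor of a zero-error, unit-weight hypothesis (its
  configuration term); **residual cost** = null − total. A large residual
  indicates the fit–activity correlation is unlikely to be accidental.

The bit *magnitudes* of proprietary implementations are not reproducible —
their constants are unpublished — so only the published residual-cost
identity and the decomposition invariants are compared against printed
values; everything else about the cost model is validated by
parameter-recovery properties.

# Validation

* **Fischer randomization** (`fischer_randomization()`): activities are
  permuted uniformly `round(100/(100−c)) − 1` times (19 at the 95% level),
  the generator is re-run on each scramble, and the original is declared
  significant only if it strictly beats every scramble. The default
  comparison is the training correlation with total cost as tie-breaker;
  comparing costs alone is supported, since either convention is found in
  practice.
* **Test-set prediction** (`test_set_correlation()`): squared Pearson
  correlation between estimated and observed pIC50, with no-match
  molecules estimated at the intercept.
* **Enrichment** (`enrichment_metrics()`): from counts D, A, Ht, Ha it
  reports %Y = 100·Ha/Ht (yield of actives), %A = 100·Ha/A (ratio of
  actives retrieved), E = (Ha/Ht)/(A/D), the Güner–Henry score
  GH = (Ha(3A + Ht)/(4·Ht·A))·(1 − (Ht − Ha)/(D − A)), and the false
  negative/positive counts. GH lies in [0, 1] by construction (the tests
  sweep every valid count combination with D ≤ 60) and is 1 exactly for an
  ideal screen. Descriptions of %Y and %A as "recall" and "precision" are
  used inconsistently in the literature; this package follows the
  bracketed formulas above.

# Virtual screening

`screen_library()` runs the funnel: (1) Lipinski rule-of-five filter —
strict inequalities (MW > 500, logP > 5, donors > 5, acceptors > 10), one
violation rejects by default, a multi-violation policy is a parameter
because published screens differ on this point; (2) conformer preparation;
(3) pharmacophore query with zero omitted features. Hits are ranked by fit
(ties by id, for reproducibility) and stage counts are reported as a
funnel; unparseable records are counted as rejected rather than silently
dropped.

Consensus scoring over external docking-score matrices
(`fit_consensus()`/`predict_consensus()`) is a transparent re-design:
orientation-corrected z-scores per scoring function, averaged under
non-negative weights summing to one, calibrated to pIC50 by least squares.
Predictions are invariant to positive affine rescaling of any single
scorer column and to column order. Zero-variance scorers are dropped with
a warning (or rejected in strict mode). No claim is made of reproducing any
proprietary consensus function; published score tables are consumed as
data through `load_score_matrix()`.

# The synthetic benchmark generators

Real inputs for this workflow (a curated inhibitor series, a large
screening database, a decoy set) are not redistributable, so the package
ships seeded generators of abstract *pseudo-ligands*: conformers given
directly as typed feature-point sets. This isolates the mapping,
generation, validation and screening logic from chemistry perception; a
small set of real SMILES exercises the chemistry path separately.

Design of the generators, and why:

* `make_pharmacophore()`: centers uniform in a sphere of radius 5 Å (a
  typical small-molecule half-extent), pairwise separation at least twice
  the tolerance so spheres do not overlap.
* `make_actives()`: the truth's points under Gaussian jitter (default
  0.4 Å, i.e. well inside the 1.6 Å tolerance), plus 7 distractor points
  (a drug-like molecule presents roughly a dozen perceivable features),
  3 conformers per ligand (flexibility), each under a random rigid
  transform. Draws are resampled until the active maps the truth above the
  fit threshold (default 60% of the maximum), so the postcondition is
  guaranteed rather than probable.
* `make_decoys()`: *structurally matched* decoys — each decoy is built
  exactly like an active but around its own private random scaffold
  arrangement, so actives and decoys are indistinguishable in point count,
  kind composition, extent and conformer count; only the specific planted
  geometry differs. Decoys that map the truth are resampled (the observed
  decoy-versus-truth match rate is zero). This mirrors the logic of
  property-matched decoy sets: decoy molecules have pharmacophoric content
  of their own, just not the active arrangement. An earlier design with
  uniformly random decoy point clouds was rejected because a random query
  then retrieved actives preferentially — the benchmark, not the method,
  was discriminating.
* `make_training_set()`: 62 ligands (the scale of a typical quantitative
  training series) at graded degradation: per-ligand jitter uniform in
  0.1–0.8 Å and knockout depths cycling {0, 0, 1, 2, all} planted features.
  Activities follow pIC50 = 0.9 · fit + 4 + N(0, 0.3): a full match sits
  near pIC50 8.5, a non-binder near 4, guaranteeing the canonical
  requirements (at least 16 molecules, more than four orders of magnitude
  of activity) and a non-trivial lead/moderate/inactive partition.

What the generators deliberately do **not** emulate: real conformational
energetics, feature perception noise, correlated activity errors,
activity cliffs, or the physicochemical property matching of real decoy
sets (matching is defined on point-set statistics instead). Passing the
planted-recovery and enrichment properties therefore demonstrates the
correctness of the machinery under its own generative model, not
performance on experimental data.

# Numerical choices and degenerate inputs

* Feasibility slack 1e-9 on tolerance checks; fit ties at 1e-12.
* Zero-variance fit vectors raise an error (degenerate hypothesis) rather
  than returning an undefined regression.
* Conformer deduplication at 0.5 Å heavy-atom RMSD after superposition;
  the published workflow's settings (250 conformers, 20 kcal/mol window)
  are the defaults.
* The internal 3D builder uses idealised geometry (standard bond lengths,
  tetrahedral/trigonal angles, planar rings) and a simple Lennard-Jones
  style steric energy; it is deterministic by construction, which the
  conformer-ensemble contract requires, and is adequate for toleranced
  pharmacophore work but not a substitute for force-field conformers.
  Bridged and spiro ring systems are placed approximately.
* Feature directionality (donor vectors, ring normals) is perceived and
  reported but not used in scoring; the fit model is distance-only.
* An optional fit cap based on the reference ligands' own fit values is
  deliberately not applied: raw fits are reported, and any capping rule is
  left to the caller, since published descriptions of that option are too
  vague to implement faithfully.

# Problem sizes

The shipped tests run the planted-recovery study at 20 replicates of 62
training ligands, the enrichment study on one 3,606-molecule benchmark
with 66 actives, the Fischer null study at 20 replicates of 19 scrambles
over 20-ligand sets, and the oracle comparison on two- and three-feature
fixtures; these sizes keep the full suite comfortably within a coffee
break on a single core while leaving every statistical margin wide.

# Known limitations

* No excluded-volume spheres and no field-based (electrostatic or shape)
  scoring.
* The pairwise-distance pruning bound is loose for very large tolerances;
  annealing therefore clamps tolerances at 2.5 Å.
* Charge handling in the perception rules is minimal (formal charges from
  connection tables are ignored); strongly charged species will be
  perceived by their neutral-atom rules.
* The consensus module presumes scorer orientation is declared by the
  caller; it cannot infer from data whether a scoring function is
  higher-better.
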