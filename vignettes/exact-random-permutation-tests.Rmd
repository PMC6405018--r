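---
title: "Exact tests with random transformations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact tests with random transformations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permexact)
```

## The model

Let `X` be a data vector and `G` a finite set of invertible maps on the
sample space, closed under composition and containing the identity and
all inverses — a *group*.  The null hypothesis tested throughout is
invariance: the joint law of the statistics `(T(gX) : g ∈ G)` is
unchanged when `X` is replaced by `g'X` for any `g' ∈ G`.  Concretely:

* **Two-sample design** (`two_sample_design(n)`): `X ∈ R^{2n}`, cases in
  positions `1..n`, controls after; `T(X) = Σ cases − Σ controls`;
  `G` = all `(2n)!` index permutations.  iid sampling under the null
  implies the invariance.
* **Sign-flip design** (`sign_flip_design(n)`): `G = {−1,+1}^n` acting
  elementwise, `T = sum`; the null is symmetry of the law of `X` about 0.
* **Rotation design** (`rotation_design`): `G` = SO(2), `T(X) = X₁`;
  the null is rotational invariance (e.g. a centred spherical Gaussian).

The basic test sorts the `#G` values `T(gX)` and rejects when
`T(X) > T^{(k)}(X)` with `k = ⌈(1−α)#G⌉`.  Its validity is purely
group-theoretic: `Gg = G` makes the threshold `T^{(k)}` invariant under
the group action, so conditionally on the orbit
`O_X = {gX : g ∈ G}` at most a fraction `α` of orbit points can reject.
The package refuses to run this rule over a set whose group certificate
is not `verified_group` (`verify_group()` performs the `O(#G²)` axiom
check) unless the caller passes an explicit override — non-group sets
are exactly how anti-conservative "permutation" tests arise.

## Randomized (boundary) adaptation

With discrete data, or when `α#G` is not attainable by the rank
arithmetic, the strict rule is conservative.  The randomized adaptation
rejects at the boundary `T(X) = T^{(k)}` with probability

\[ a = \frac{\alpha\,\#G - M^+}{M^0}, \]

where `M⁺` and `M⁰` count statistics strictly above and equal to the
threshold.  The resulting rejection probability is exactly `α` for any
data distribution satisfying the invariance.  We apply the formula as
printed even when `α#G` is non-integral (a fractional `a` is its
purpose) and clip to `[0,1]` only as a floating-point guard.

## Random transformations

When `#G` is astronomically large, draw `g_2, …, g_w` uniformly from `G`
— iid ("with replacement") or distinct and excluding the identity
("without replacement") — and *prepend the identity*:
`G' = (id, g_2, …, g_w)`.  The same order-statistic rule with
`k' = ⌈(1−α)w⌉` then has level at most `α`: conditionally on the orbit,
`(g_1X, …, g_wX)` with `g_1 = id` behaves like a Monte Carlo sample from
the orbit-conditional null that *includes the observed point*.  The
boundary-randomized version (`randomized_random_perm_test()`,
`a = (wα − M⁺)/M⁰` with counts over the `w` drawn statistics) is exactly
`α` with no continuity assumption — ties are absorbed by `M⁰`.

Uniform sampling from implicit groups uses direct constructions: a
uniform shuffle for the symmetric group, iid fair signs for `{−1,+1}^n`.
Without-replacement sampling from implicit groups is realized by
rejection sampling with duplicate detection on a canonical payload
encoding (exact for permutations and signs, 12-decimal rounding for
rotations).  This choice is ours — no prescription exists in the
underlying theory — and the proposal loop aborts after `1000·w`
rejections, which is never reached in the intended regime `w ≪ #G`.

## Equivalence classes and representative sampling

For the two-sample statistic with continuous data the group partitions
into `m = C(2n, n)` classes of equal size `n!·n!`: two permutations give
the same statistic exactly when they move the same set of original
indices into the case block.  Class labels (`class_of_permutation()`)
are sorted index tuples; the canonical representative of a class is the
order-preserving placement of its case-subset.  Drawing representatives
of *distinct* classes without replacement (plus the identity) makes the
test exact for every `α ∈ {0/w, …, (w−1)/w}` — the continuous-data
analogue of using the full group, at a fraction of the cost.  The
rejection law of the full-group test under this partition is
`⌊αm⌋/m`, which the harness verifies empirically at `n = 3`
(`m = 20`): `α = 0.03` can never reject, `α ∈ {0.05, 0.08}` both give
exactly `0.05`.

## Finite subsets of infinite groups

For an infinite group (rotations), take any finite subset `G*`, draw `h`
uniformly from `G*`, and compare `T(X)` with the order statistics of
`T` over the shifted set `G*h⁻¹`.  The shift is what restores the
group-invariance argument; when `G*` happens to be a group,
`G*h⁻¹ = G*` and the procedure degenerates to the basic test (the test
suite checks this exhaustively over all `h` for the 8-element sign-flip
group).

## p-values

Conventions are fixed once, in a central comparison utility:
counts `D = #{g : T(gX) ≥ T(X)}` and `B = #{j : T(g_jX) ≥ T(X)}` use
`≥`; rejection uses strict `>`; the randomized p-value splits counts
into `>` and `=` parts:

\[ p' = \frac{\#\{T(g_jX) > T(X)\}}{w} + u\,\frac{\#\{T(g_jX) = T(X)\}}{w},
   \qquad u \sim U[0,1]. \]

`p' ≤ α` if and only if the boundary-randomized test with the same `u`
rejects, hence `p'` is exactly uniform under the null.  Its upper bound
(`≥`-count over the identity-adjoined vector divided by `w`) is a valid
weak p-value and equals `(B+1)/(w+1)` under the usual convention.  The
naive `p̂ = B/w` is an unbiased *estimate* of the full-group p-value but
not a valid p-value (`P(p̂ = 0) > 0`); it is implemented, permanently
flagged `not_valid_alone`, and hidden behind a double-opt-in in the CLI.
The exact inflation at cutoff `c < 1/w` is
`P(B = 0) = N^{-(w+1)} Σ_{j<N} j^w` for a continuous orbit of `N`
distinct values (`naive_zero_oracle()`), which the harness reproduces
within Monte Carlo error — e.g. `≈ 0.090` for `N = 1024, w = 10`,
nearly double the nominal `c = 0.05`.

## Synthetic data: the stated world

The generator families are deliberately minimal:

* `gaussian` — iid N(0,1); exchangeable and symmetric; the default
  continuous null everywhere.
* `exponential_centered` — iid centred exponential; exchangeable but
  **not** symmetric about zero, so it serves only two-sample designs.
* `bernoulli_signed` — iid uniform `{−1,+1}`; symmetric, tie-prone.
* `integer_ties` — iid uniform on a small integer support, default
  `{0,1,2}`; forces heavy ties without degenerate orbits.  The default
  support is kept for exchangeable (two-sample) arms; sign-flip arms use
  the centred support `{−1,0,1}`, because symmetry about zero is the
  sign-flip null — a non-symmetric support would violate the hypothesis
  being simulated rather than stress-test the procedure.

Alternatives are location shifts (cases shifted for two-sample, all
entries for sign-flip).  The generators emulate exchangeability,
symmetry and discreteness; they do not emulate dependence, heterogeneous
variances or outlier contamination, so a green harness establishes the
*level* claims under the stated invariances and nothing about behaviour
when the invariance itself fails.

All level claims are estimated with fresh transformation draws on every
replicate — the unconditional probability statements average over both
data and draws.  Acceptance bands are `±3` binomial standard errors at
the replicate count actually used (50,000 for most criteria), derived
from the binomial model rather than hard-coded.

## The balanced-permutation negative control

Balanced permutations exchange exactly `n/2` cases with `n/2` controls.
The package exposes two constructions: one canonical representative per
balanced case-subset (`C(n, n/2)²` elements — sufficient for the
group-axiom counterexample, since already the `n = 2` set plus the
identity violates closure), and the full set of all permutations whose
case-subset is balanced (`C(n, n/2)²·n!·n!` elements), which is the set
actually discussed in the applied literature.  The negative-control
demonstration uses the **full** set: at `n = 4`, `α = 0.05` the
rejection rule over it plus the identity has type-I error `≈ 0.068`
(versus `3/70 ≈ 0.043` for the honest full group on identical data), a
decisive inflation.  The representative-level set also inflates relative
to its own exchangeable benchmark (`≈ 0.051` versus `1/37 ≈ 0.027`) but
happens to sit near the nominal 0.05 at this design size, which would
understate the danger; the full set is both the literature's object and
the clearer demonstration.

## Numerical choices

* **Threshold index.** `k = ⌈(1−α)N⌉` is computed as
  `N − floor(αN + 1e−9)`, algebraically identical on `α ∈ [0,1)` and
  immune to binary-representation noise such as `0.9 × 10 > 9`.
* **Ties.** Detected by exact equality by default (`tol = 0`):
  statistics are sums of one multiset of inputs, so permutation/sign
  ties are bit-exact.  A configurable absolute tolerance exists for
  rotation designs, where recomposition can round.
* **Rotation validity.** Orthogonality and unit determinant are checked
  at `1e−10`; rotations are constructed, not measured.
* **RNG.** Every randomized operation takes an explicit seed and leaves
  the caller's RNG state untouched; auxiliary uniforms for boundary
  decisions consume a derived substream, so toggling randomization does
  not shift transformation draws.  Seed records ride along in every
  result.
* **Sorting.** Only the counts `M⁺`/`M⁰` enter decisions, so tie order
  within the sort is irrelevant (asserted by a shuffle-stability test).

## Engines

`estimate_type1()` has two engines: a *reference* engine that loops the
object-level test functions (the oracle), and a *vectorized* engine with
per-design matrix kernels (statistics for all replicates at once;
equivalence-class arithmetic replaces enumeration of `(2n)!`
permutations, using the fact that the sorted full-group vector is the
sorted class vector with each value repeated `n!·n!` times).  The test
suite checks the kernels against the object-level rules on identical
inputs and the two engines against each other statistically; the
acceptance criteria run on the vectorized engine at 20,000–50,000
replicates in seconds.

## Limitations

* Equal group sizes only in the two-sample design; unequal sizes are an
  extension point, not implemented.
* Rotation designs are 2-dimensional; higher-dimensional rotation
  subsets would need a uniform-on-SO(d) constructor.
* Statistics are one-sided as supplied; callers wanting two-sided tests
  pass e.g. `function(x) abs(sum(x))`.
* No multiple-testing wrappers, no confidence intervals by test
  inversion, no power/consistency theory — the package proves (by
  simulation) level and exactness, which is what the underlying theory
  guarantees.
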