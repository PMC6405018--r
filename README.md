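# permexact

Exact permutation and transformation tests with **random** transformations.

## The problem

Permutation tests compare an observed test statistic `T(X)` with the
statistics `T(gX)` obtained by transforming the data with maps `g` from a
finite set `G` — index permutations (two-sample exchangeability), sign
flips (one-sample symmetry), or rotations (spherical invariance).  Two
things are routinely gotten wrong in practice:

1. **The group structure is not optional.**  The level guarantee of the
   permutation test rests on `Gg = G` for every `g ∈ G`, which holds
   exactly when `G` is a group under composition (identity, inverses,
   closure).  Plausible-looking non-group subsets — the classic example
   being *balanced permutations* — give anti-conservative tests.
2. **Random permutations need the identity.**  When `#G` is too large to
   enumerate, one uses `w` random transformations.  The naive estimated
   p-value `p̂ = B/w` (with `B = #{j : T(g_jX) ≥ T(X)}` over `w` random
   draws) has positive probability of being `0` and is therefore *not* a
   valid p-value — catastrophically so under Bonferroni-small cutoffs.
   But if the identity is adjoined, `G' = (id, g_2, …, g_w)` with the
   `g_j` uniform on the group (with or without replacement), then the
   test that rejects when `T(X) > T^{(k')}(X, G')`,
   `k' = ⌈(1−α)w⌉`, has level at most `α`; equivalently
   `(B+1)/(w+1)` is a valid (weak) p-value.

This package implements the complete family of such tests and p-values,
for three concrete designs (two-sample difference of sums, one-sample
sign flipping, planar rotations):

| procedure | function | guarantee |
|---|---|---|
| full-group test | `full_group_test()` | level ≤ α; exact at multiples of 1/m under the class partition |
| randomized full-group (Hoeffding) | `hoeffding_randomized_test()` | exactly α, boundary rejected with prob. `a = (α#G − M⁺)/M⁰` |
| random draws + identity | `random_perm_test()` | level ≤ α |
| class representatives | `representative_random_test()` | exact on the grid `{0/w, …, (w−1)/w}` (without replacement, continuous data) |
| randomized random draws | `randomized_random_perm_test()` | exactly α, `a = (wα − M⁺)/M⁰`, ties allowed |
| subset shift `G*h⁻¹` | `subset_shift_test()` | level ≤ α for any finite subset of a (possibly infinite) group |
| plain Monte Carlo | `monte_carlo_test()` | exact, but needs a fully specified null |

p-values: `full_group_pvalue()` (`D/#G`), `pvalue_plus_one()`
(`(B+1)/(w+1)`), `randomized_pvalue()` (`p'`, exactly uniform under the
null), `pvalue_upper()` (its simple upper bound), and the deliberately
flagged `pvalue_naive()` (`B/w`).

A simulation harness (`estimate_type1()`, `simulate_pvalues()`,
`phipson_smyth_demo()`, `balanced_demo()`) turns every one of these
guarantees into an assertable experiment; the test suite runs them at
up to 50,000 replicates with 3-standard-error binomial bands.

## Worked example

One-sample symmetry test with 999 random sign flips (identity adjoined):

```r
library(permexact)
x <- c(1.83, 0.62, 1.44, 1.21, 0.95, 1.70)
drawn <- draw_transformations(signflip_group(6), w = 999, seed = 7)
random_perm_test(x, drawn, statistic = sum, alpha = 0.05)
#> Transformation test (random_transformations)
#>   observed T = 7.75, threshold T(950) = 5.85, alpha = 0.05
#>   reject: TRUE
pvalue_report(x, drawn, statistic = sum, u = 0.5)
#> p-value report
#>   B: 16
#>   w: 999
#>   p_plus_one: 0.01701702
#>   p_naive: 0.01603206
#>   p_randomized: 0.008508509
#>   p_upper: 0.01701702
#>   u: 0.5
```

The observed sum 7.75 exceeds the 950th of the 999 sorted statistics
(`k' = ⌈0.95·999⌉ = 950`), so symmetry about zero is rejected at
`α = 0.05`; the safe p-value is `(B+1)/(w+1) = 17/1000`.

Verifying exactness of the boundary-randomized random test
(`n = 8` sign-flip design, `w = 20` draws, 50,000 null replicates):

```r
estimate_type1(config_random(sign_flip_design(8), 20, randomized = TRUE),
               null_model("gaussian", 8), reps = 50000, alpha = 0.05, seed = 1)
#> simulation_result: 2579 / 50000 rejections; estimate = 0.05158 (se 0.000989136 )
```

And the balanced-permutation warning, as a paired experiment on
identical data (the non-group set inflates the type-I error; the honest
full group does not):

```r
bd <- balanced_demo(n = 4, alpha = 0.05, reps = 50000, seed = 1,
                    acknowledge_nongroup = TRUE)
#> balanced: 0.06786   group: 0.04228   binom p: 3.18e-68
```

## Command line

```sh
exec/permtest test   --input data.csv --w 999 --alpha 0.05 --seed 7
exec/permtest pvalue --input data.csv --w 999 --seed 7 [--randomized]
exec/permtest simulate type1 --design sign_flip --n 8 --test random --w 20 \
    --randomized --alpha 0.05 --reps 50000 --seed 1
exec/permtest demo phipson-smyth --w 10 --n 10 --c 0.05 --reps 50000 --seed 1
exec/permtest demo balanced --n 4 --alpha 0.05 --reps 50000 --seed 1 \
    --acknowledge-nongroup
```

Input is CSV/TSV with a numeric `value` column and, for the two-sample
design, a two-level `group` column (first-appearing level = cases, equal
sizes).  Output is JSON at full precision, including the seed record
needed to replay the exact decision.  `B/w` is only printed under
`--unsafe-naive-p`, and non-group sets only run under an explicit
acknowledgement flag — each with a machine-readable warning record.

## Vignette

`vignettes/exact-random-permutation-tests.Rmd` documents the model and
its assumptions, all rejection rules and p-value constructions, the
synthetic-data families, numerical conventions (tie handling, threshold
index arithmetic, RNG contracts), and known limitations.
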