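# Test procedures.  All variants share one order-statistic decision core:
# sort the statistics T(g x) over the transformation collection, take the
# k-th smallest with k = ceil((1 - alpha) * N), and reject when the
# observed statistic strictly exceeds it.  The randomized (Hoeffding-type)
# variants additionally reject with probability a at the boundary
# T(x) = T^{(k)}, which makes the rejection probability exactly alpha.

# ceil((1 - alpha) * N) computed as N - floor(alpha * N), which is
# algebraically identical for alpha in [0, 1) and immune to the
# floating-point noise of (1 - alpha) * N.
rank_threshold_index <- function(alpha, N) {
  as.integer(N - floor(alpha * N + 1e-9))
}

# Comparison conventions, centralized so no formula can drift:
# rejection uses strict >, the counts D and B use >=, and the randomized
# p-value splits into > and = parts.  tol = 0 by default: statistics built
# from the same multiset of inputs tie bit-exactly under permutation and
# sign actions; rotations may pass a small tolerance.
cmp_gt <- function(a, b, tol = 0) a > b + tol
cmp_eq <- function(a, b, tol = 0) abs(a - b) <= tol
cmp_ge <- function(a, b, tol = 0) a >= b - tol

# Shared decision core on a vector of statistics.
order_stat_decision <- function(stats, observed, alpha, tol = 0) {
  N <- length(stats)
  k <- rank_threshold_index(alpha, N)
  thr <- sort(stats, method = "quick")[k]
  m_plus <- sum(cmp_gt(stats, thr, tol))
  m_zero <- sum(cmp_eq(stats, thr, tol))
  list(k = k, threshold = thr, m_plus = m_plus, m_zero = m_zero,
       reject_strict = cmp_gt(observed, thr, tol), N = N)
}

new_perm_test_result <- function(method, reject, alpha, dec, observed,
                                 a = NULL, pvalue = NULL, seed_record = NULL,
                                 w = NULL, scheme = NULL) {
  structure(list(method = method, reject = reject, alpha = alpha,
                 k = dec$k, threshold_value = dec$threshold,
                 observed = observed, a = a,
                 m_plus = dec$m_plus, m_zero = dec$m_zero,
                 pvalue = pvalue, seed_record = seed_record,
                 w = if (is.null(w)) dec$N else w, scheme = scheme),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat("Transformation test (", x$method, ")\n", sep = "")
  cat("  observed T = ", format(x$observed), ", threshold T(", x$k, ") = ",
      format(x$threshold_value), ", alpha = ", x$alpha, "\n", sep = "")
  if (!is.null(x$a)) cat("  boundary randomization a =", format(x$a), "\n")
  if (!is.null(x$pvalue)) cat("  p-value:", format(x$pvalue), "\n")
  cat("  reject:", x$reject, "\n")
  invisible(x)
}

# Accept either a verified transformation_set or a group_spec; materialize
# specs.  Uncertified sets are refused unless allow_nongroup = TRUE: using
# a non-group silently is the classic way to get an anti-conservative test.
resolve_full_group <- function(G, allow_nongroup = FALSE) {
  if (inherits(G, "group_spec")) return(materialize_group(G))
  stopifnot(inherits(G, "transformation_set"))
  if (G$group_certificate != "verified_group") {
    if (!allow_nongroup)
      stop("transformation set is not a verified group (certificate: ",
           G$group_certificate,
           "); run verify_group(), or pass allow_nongroup = TRUE ",
           "if you really intend to test over a non-group set")
    warning("running a permutation test over an UNVERIFIED or NON-GROUP ",
            "transformation set; the level guarantee does not apply",
            call. = FALSE)
  }
  G
}

full_group_stats <- function(x, G, statistic) {
  vapply(G$elements, function(g) statistic(apply_transformation(g, x)),
         numeric(1))
}

#' Basic permutation test over the full group
#'
#' Computes all `#G` statistics `T(gx)`, sorts them, and rejects when the
#' observed `T(x)` strictly exceeds the `k`-th smallest with
#' `k = ceil((1 - alpha) #G)`.  Level at most `alpha` for any null under
#' which the statistic vector is invariant to every `g` in the group;
#' exact only at the multiples of `1/m` when the statistic partitions the
#' group into `m` equal equivalence classes (continuous data).
#'
#' @param x Numeric data vector.
#' @param G A verified `transformation_set` or a `group_spec`.
#' @param statistic Function mapping a data vector to a real number.
#' @param alpha Level, in `[0, 1)`.
#' @param allow_nongroup Run anyway over a non-group set (negative-control
#'   demos only; logs a warning).
#' @param tol Absolute tolerance for tie detection (default 0; see
#'   Details in the package vignette).
#' @return A `"perm_test_result"`.
#' @examples
#' full_group_test(c(2.1, 1.3, 0.7), signflip_group(3), sum, alpha = 0.25)
#' @export
full_group_test <- function(x, G, statistic, alpha, allow_nongroup = FALSE,
                            tol = 0) {
  stopifnot(alpha >= 0, alpha < 1)
  G <- resolve_full_group(G, allow_nongroup)
  stats <- full_group_stats(x, G, statistic)
  obs <- if (!is.na(G$identity_index)) stats[[G$identity_index]]
         else statistic(x)
  dec <- order_stat_decision(stats, obs, alpha, tol)
  new_perm_test_result("full_group", dec$reject_strict, alpha, dec, obs)
}

#' Randomized (Hoeffding-adapted) full-group test
#'
#' As [full_group_test()], but in the boundary case `T(x) = T^{(k)}` the
#' test rejects with probability `a = (alpha #G - M+) / M0`, where `M+`
#' and `M0` count statistics strictly above and equal to the threshold.
#' The rejection probability under the invariance null is then exactly
#' `alpha`, for any `alpha` and any (even discrete, tie-prone) data.
#'
#' @inheritParams full_group_test
#' @param seed Optional integer seed; the auxiliary uniform consumes a
#'   dedicated substream so that toggling randomization does not shift
#'   other draws.
#' @return A `"perm_test_result"` with the randomization probability `a`.
#' @export
hoeffding_randomized_test <- function(x, G, statistic, alpha,
                                      allow_nongroup = FALSE, tol = 0,
                                      seed = NULL) {
  stopifnot(alpha >= 0, alpha < 1)
  G <- resolve_full_group(G, allow_nongroup)
  stats <- full_group_stats(x, G, statistic)
  obs <- if (!is.na(G$identity_index)) stats[[G$identity_index]]
         else statistic(x)
  dec <- order_stat_decision(stats, obs, alpha, tol)
  a <- (alpha * dec$N - dec$m_plus) / dec$m_zero
  a <- min(max(a, 0), 1)               # floating-point guard only
  seed <- resolve_seed(seed)
  reject <- dec$reject_strict
  if (!reject && cmp_eq(obs, dec$threshold, tol)) {
    u <- withr::with_seed(derive_seed(seed, "boundary-u"), stats::runif(1))
    reject <- u < a
  }
  new_perm_test_result("hoeffding_randomized", reject, alpha, dec, obs,
                       a = a, seed_record = list(seed = seed))
}

#' Random-transformation test with the identity adjoined
#'
#' Applies the order-statistic rejection rule to the `w` statistics
#' `T(g_j x)` over a drawn vector `(id, g_2, ..., g_w)`.  Provided the
#' first entry is the identity and the remaining entries are uniform on
#' the group (with or without replacement), the rejection probability
#' under the invariance null is at most `alpha` — the test is a
#' conditional Monte Carlo test on the orbit of `x`.
#'
#' @param x Numeric data vector.
#' @param drawn A `"drawn_transformations"` vector; its first element must
#'   be the identity.
#' @param statistic Statistic function.
#' @param alpha Level in `[0, 1)`.
#' @param tol Tie tolerance (default 0).
#' @return A `"perm_test_result"`.
#' @export
random_perm_test <- function(x, drawn, statistic, alpha, tol = 0) {
  stopifnot(inherits(drawn, "drawn_transformations"), alpha >= 0, alpha < 1)
  if (!is_identity_transformation(drawn$transformations[[1L]]))
    stop("the first drawn transformation must be the identity; ",
         "adjoining it is what makes the test level-alpha")
  stats <- vapply(drawn$transformations,
                  function(g) statistic(apply_transformation(g, x)), numeric(1))
  obs <- stats[[1L]]
  dec <- order_stat_decision(stats, obs, alpha, tol)
  new_perm_test_result("random_transformations", dec$reject_strict, alpha,
                       dec, obs, seed_record = drawn$seed_record,
                       w = drawn$w, scheme = drawn$scheme)
}

#' Random test over equivalence-class representatives
#'
#' Draws class representatives for a two-sample design (one fixed
#' permutation per case-subset) via [representatives()] and applies the
#' random-transformation rejection rule.  Under without-replacement
#' sampling and continuous data the test is exact for every `alpha` in
#' `{0/w, 1/w, ..., (w-1)/w}`.
#'
#' @param x Data vector of length `2n`, cases first.
#' @param design A `two_sample_design`.
#' @param w Total number of transformations, identity included.
#' @param scheme Representative sampling scheme.
#' @param alpha Level in `[0, 1)`.
#' @param statistic Statistic function; defaults to the design's.
#' @param seed Optional integer seed.
#' @return A `"perm_test_result"`.
#' @export
representative_random_test <- function(x, design, w,
                                       scheme = c("without_replacement",
                                                  "with_replacement"),
                                       alpha,
                                       statistic = design_statistic(design),
                                       seed = NULL) {
  scheme <- match.arg(scheme)
  drawn <- representatives(design, w, scheme, seed = seed)
  random_perm_test(x, drawn, statistic, alpha)
}

#' Randomized random-transformation test (exact for any alpha)
#'
#' The Hoeffding boundary adaptation applied to random draws: reject when
#' `T(x) > T^{(k')}`, and when `T(x) = T^{(k')}` reject with probability
#' `a = (w alpha - M+) / M0`, with `M+` and `M0` counted over the `w`
#' drawn statistics.  The rejection probability under the invariance null
#' is exactly `alpha`, with no continuity assumption — ties are absorbed
#' by `M0`.
#'
#' @inheritParams random_perm_test
#' @param seed Optional integer seed for the auxiliary uniform.
#' @param u Optional auxiliary uniform in `[0, 1]`; supply it to tie the
#'   decision to [randomized_pvalue()] (reject iff `p' <= alpha`).
#' @return A `"perm_test_result"` with the randomization probability `a`.
#' @export
randomized_random_perm_test <- function(x, drawn, statistic, alpha, tol = 0,
                                        seed = NULL, u = NULL) {
  stopifnot(inherits(drawn, "drawn_transformations"), alpha >= 0, alpha < 1)
  if (!is_identity_transformation(drawn$transformations[[1L]]))
    stop("the first drawn transformation must be the identity; ",
         "adjoining it is what makes the test level-alpha")
  stats <- vapply(drawn$transformations,
                  function(g) statistic(apply_transformation(g, x)), numeric(1))
  obs <- stats[[1L]]
  dec <- order_stat_decision(stats, obs, alpha, tol)
  a <- (dec$N * alpha - dec$m_plus) / dec$m_zero
  a <- min(max(a, 0), 1)
  seed <- resolve_seed(seed)
  if (is.null(u) && cmp_eq(obs, dec$threshold, tol) && !dec$reject_strict)
    u <- withr::with_seed(derive_seed(seed, "boundary-u"), stats::runif(1))
  reject <- dec$reject_strict ||
    (cmp_eq(obs, dec$threshold, tol) && !is.null(u) && a > u)
  new_perm_test_result("randomized_random_transformations", reject, alpha,
                       dec, obs, a = a,
                       seed_record = list(seed = seed,
                                          draw = drawn$seed_record),
                       w = drawn$w, scheme = drawn$scheme)
}

#' Subset-shift test for finite subsets of a possibly infinite group
#'
#' Draws `h` uniformly from the finite subset `G*`, evaluates the
#' statistics over the shifted set `{g o h^{-1} : g in G*}`, and rejects
#' when `T(x)` strictly exceeds the `k*`-th smallest with
#' `k* = ceil((1 - alpha) #G*)`.  Level at most `alpha` whenever the data
#' law is invariant under the enclosing group; when `G*` is itself a
#' group, `G* h^{-1} = G*` and the test coincides with the basic
#' full-group test for every `h`.
#'
#' @param x Data vector.
#' @param G_star A nonempty `transformation_set` (any finite subset; no
#'   group certificate required — that is the point of the scheme).
#' @param statistic Statistic function.
#' @param alpha Level in `[0, 1)`.
#' @param seed Optional integer seed for the draw of `h`.
#' @param h_index Force a specific `h` (1-based index into `G*`); used by
#'   exhaustive equivalence checks.
#' @param tol Tie tolerance; rotations recompose with rounding, so a small
#'   positive value may be warranted there.
#' @return A `"perm_test_result"`; the drawn index is recorded in
#'   `seed_record$h_index`.
#' @export
subset_shift_test <- function(x, G_star, statistic, alpha, seed = NULL,
                              h_index = NULL, tol = 0) {
  stopifnot(inherits(G_star, "transformation_set"), alpha >= 0, alpha < 1)
  N <- length(G_star$elements)
  seed <- resolve_seed(seed)
  if (is.null(h_index))
    h_index <- withr::with_seed(seed, sample.int(N, 1L))
  h_inv <- inverse(G_star$elements[[h_index]])
  stats <- vapply(G_star$elements,
                  function(g) statistic(apply_transformation(compose(g, h_inv), x)),
                  numeric(1))
  obs <- statistic(x)
  dec <- order_stat_decision(stats, obs, alpha, tol)
  new_perm_test_result("subset_shift", dec$reject_strict, alpha, dec, obs,
                       seed_record = list(seed = seed, h_index = h_index),
                       w = N)
}

#' Plain Monte Carlo test (for contrast with permutation tests)
#'
#' Draws `w - 1` fresh datasets from a fully specified null distribution,
#' sets `X_1 = x`, and applies the same order-statistic rejection rule.
#' Unlike a permutation test, the comparison datasets are independent
#' draws from the null itself — not transformations of the observed data —
#' so this test requires the null to be completely known.
#'
#' @param x Observed data vector.
#' @param null_sampler Zero-argument function returning one dataset drawn
#'   from the null distribution.
#' @param statistic Statistic function.
#' @param w Total number of datasets including the observed one.
#' @param alpha Level in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return A `"perm_test_result"`.
#' @export
monte_carlo_test <- function(x, null_sampler, statistic, w, alpha,
                             seed = NULL) {
  stopifnot(alpha >= 0, alpha < 1, w >= 1)
  seed <- resolve_seed(seed)
  stats <- withr::with_seed(seed, {
    c(statistic(x),
      if (w > 1L) vapply(seq_len(w - 1L),
                         function(i) statistic(null_sampler()), numeric(1)))
  })
  obs <- stats[[1L]]
  dec <- order_stat_decision(stats, obs, alpha)
  new_perm_test_result("monte_carlo", dec$reject_strict, alpha, dec, obs,
                       seed_record = list(seed = seed), w = w)
}

# Serialize a test result (mirrors the result fields; enough to replay).
test_result_to_list <- function(r) {
  out <- unclass(r)
  out[!vapply(out, is.null, logical(1))]
}
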