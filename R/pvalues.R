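# p-value constructions.  Conventions, centralized in cmp_* (perm-tests.R):
# the counts D and B use >=, rejection uses strict >, and the randomized
# p-value p' splits its counts into a strict > part and an = part weighted
# by an auxiliary uniform u.

new_pvalue_report <- function(...) {
  fields <- list(...)
  structure(fields, class = "pvalue_report")
}

#' @export
print.pvalue_report <- function(x, ...) {
  cat("p-value report\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.null(v)) next
    cat("  ", nm, ": ", paste(format(v), collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Full-group permutation p-value D / #G
#'
#' Counts `D = #{g in G : T(gx) >= T(x)}` over the whole group and returns
#' `p = D / #G`.  `D >= 1` always, since the identity contributes
#' `T(x) >= T(x)`.  For continuous data whose statistic separates the
#' equivalence classes, `D` has a uniform distribution over the attainable
#' values and `D / #G` is the classical permutation p-value; in general it
#' is a p-value in the weak sense (`P(p <= c) <= c`).
#'
#' @inheritParams full_group_test
#' @return A `"pvalue_report"` with fields `D`, `p_full`, `w` (= `#G`).
#' @export
full_group_pvalue <- function(x, G, statistic, allow_nongroup = FALSE,
                              tol = 0) {
  G <- resolve_full_group(G, allow_nongroup)
  stats <- full_group_stats(x, G, statistic)
  obs <- if (!is.na(G$identity_index)) stats[[G$identity_index]]
         else statistic(x)
  D <- sum(cmp_ge(stats, obs, tol))
  new_pvalue_report(D = D, w = length(stats), p_full = D / length(stats))
}

#' Count B: how many drawn statistics reach the observed one
#'
#' `B = #{j : T(g_j x) >= T(x)}` over a supplied list of transformations.
#' Whether the identity is among the draws is the caller's choice and is
#' recorded in the result's `"identity_included"` attribute.
#'
#' @param x Data vector.
#' @param transforms List of transformations, or a
#'   `"drawn_transformations"` object.
#' @param statistic Statistic function.
#' @param tol Tie tolerance.
#' @return Integer count `B`.
#' @export
count_B <- function(x, transforms, statistic, tol = 0) {
  if (inherits(transforms, "drawn_transformations"))
    transforms <- transforms$transformations
  if (length(transforms) == 0L) stop("transforms must be nonempty")
  obs <- statistic(x)
  stats <- vapply(transforms, function(g) statistic(apply_transformation(g, x)),
                  numeric(1))
  B <- sum(cmp_ge(stats, obs, tol))
  attr(B, "identity_included") <-
    any(vapply(transforms, is_identity_transformation, logical(1)))
  B
}

#' The (B+1)/(w+1) p-value
#'
#' Valid (weak) p-value whenever the `w` transformations behind `b` are
#' uniform random draws from a group — with replacement, or without
#' replacement from the group minus the identity.  Equivalent to adjoining
#' the identity to the draws and dividing the `>=`-count by `w + 1`.
#'
#' @param b Observed count `B` (in `0..w`).
#' @param w Number of random draws.
#' @return `(b + 1) / (w + 1)`.
#' @export
pvalue_plus_one <- function(b, w) {
  stopifnot(w >= 1)
  if (b < 0 || b > w) stop("b must lie in 0..w")
  (b + 1) / (w + 1)
}

#' The naive estimated p-value B / w (not valid on its own)
#'
#' `B / w` is an unbiased estimate of the full-group p-value `D / #G`, but
#' it is *not* a valid p-value: it has strictly positive probability of
#' equalling 0, so `P(p_hat <= c)` can far exceed `c` — catastrophically so
#' under small cutoffs such as Bonferroni-corrected thresholds.  The
#' return value carries attribute `not_valid_alone = TRUE` and the CLI
#' refuses to print it without an explicit unsafe flag.
#'
#' @param b Observed count `B`.
#' @param w Number of random draws (must be positive).
#' @return `b / w`, flagged.
#' @export
pvalue_naive <- function(b, w) {
  if (w == 0) stop("w must be positive")
  if (b < 0 || b > w) stop("b must lie in 0..w")
  structure(b / w, not_valid_alone = TRUE)
}

#' Randomized p-value p'
#'
#' `p' = #{T(g_j x) > T(x)}/w + u * #{T(g_j x) = T(x)}/w` over a
#' Definition-2 style drawn vector (identity first, so the equality count
#' is at least 1), with `u` uniform on `[0, 1]`.  `p' <= alpha` exactly
#' when the randomized random-transformation test with the same `u`
#' rejects, and `p'` is exactly uniform on `[0, 1]` under the invariance
#' null — no continuity assumption needed.
#'
#' @param x Data vector.
#' @param drawn A `"drawn_transformations"` vector (identity first).
#' @param statistic Statistic function.
#' @param u Auxiliary uniform in `[0, 1]` (explicit, for reproducibility;
#'   draw it from your own seeded stream).
#' @param tol Tie tolerance.
#' @return The randomized p-value, a single number in `[0, 1]`.
#' @export
randomized_pvalue <- function(x, drawn, statistic, u, tol = 0) {
  stopifnot(inherits(drawn, "drawn_transformations"))
  if (u < 0 || u > 1) stop("u must lie in [0, 1]")
  if (!is_identity_transformation(drawn$transformations[[1L]]))
    stop("the first drawn transformation must be the identity")
  obs <- statistic(x)
  stats <- vapply(drawn$transformations,
                  function(g) statistic(apply_transformation(g, x)), numeric(1))
  w <- length(stats)
  (sum(cmp_gt(stats, obs, tol)) + u * sum(cmp_eq(stats, obs, tol))) / w
}

#' Upper bound on the randomized p-value
#'
#' The `>=`-count over the drawn vector divided by `w`.  Dominates `p'`
#' for every `u`, is a p-value in the weak sense, and coincides with
#' `(B + 1)/(w + 1)` when the identity is adjoined to `w - 1` random draws
#' (the `>=`-count is then `B + 1` over `w` transformations).
#'
#' @inheritParams randomized_pvalue
#' @return Upper-bound p-value in `(0, 1]`.
#' @export
pvalue_upper <- function(x, drawn, statistic, tol = 0) {
  stopifnot(inherits(drawn, "drawn_transformations"))
  if (!is_identity_transformation(drawn$transformations[[1L]]))
    stop("the first drawn transformation must be the identity")
  obs <- statistic(x)
  stats <- vapply(drawn$transformations,
                  function(g) statistic(apply_transformation(g, x)), numeric(1))
  sum(cmp_ge(stats, obs, tol)) / length(stats)
}

#' Full p-value report for a drawn transformation vector
#'
#' Convenience wrapper computing, from one drawn vector `(id, g_2, ...,
#' g_w)`, the count `B` over the `w - 1` random draws, `(B+1)/w` (the
#' plus-one rule with the identity adjoined), the flagged naive `B/(w-1)`,
#' the randomized `p'` and its upper bound.
#'
#' @inheritParams randomized_pvalue
#' @param u Auxiliary uniform; if `NULL`, `p'` is omitted.
#' @return A `"pvalue_report"`.
#' @export
pvalue_report <- function(x, drawn, statistic, u = NULL, tol = 0) {
  stopifnot(inherits(drawn, "drawn_transformations"))
  if (!is_identity_transformation(drawn$transformations[[1L]]))
    stop("the first drawn transformation must be the identity")
  rand_draws <- drawn$transformations[-1L]
  b <- if (length(rand_draws)) count_B(x, rand_draws, statistic, tol) else 0L
  w_rand <- length(rand_draws)
  new_pvalue_report(
    B = as.integer(b),
    w = drawn$w,
    p_plus_one = pvalue_plus_one(as.integer(b), w_rand),
    p_naive = if (w_rand > 0) pvalue_naive(as.integer(b), w_rand) else NULL,
    p_randomized = if (!is.null(u)) randomized_pvalue(x, drawn, statistic, u, tol),
    p_upper = pvalue_upper(x, drawn, statistic, tol),
    u = u)
}
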