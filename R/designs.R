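# Concrete experimental designs: data layout + statistic + transformation
# group, plus the equivalence-class (partition) machinery of the two-sample
# design and the balanced-permutation negative control.

#' Two-sample design with equal group sizes
#'
#' Data vectors have length `2n`; positions `1..n` are cases and
#' `n+1..2n` controls.  The statistic is the difference of sums
#' `sum(cases) - sum(controls)`, which is constant on equivalence classes
#' of permutations determined solely by which original indices land in the
#' case positions.  There are `m = choose(2n, n)` such classes, each of
#' size `n! * n!`, and for continuous data the statistic separates them
#' with probability one.
#'
#' @param n Number of cases (= number of controls).
#' @return An object of class `"two_sample_design"`.
#' @export
two_sample_design <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  structure(list(n = n, len = 2L * n, kind = "index_permutation"),
            class = c("two_sample_design", "design"))
}

#' One-sample sign-flip design
#'
#' The group is `{-1, +1}^n` acting elementwise (`2^n` elements) and the
#' default statistic is the sum of the entries; the null asserts symmetry
#' of the data distribution about zero.
#'
#' @param n Data dimension.
#' @return An object of class `"sign_flip_design"`.
#' @export
sign_flip_design <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  structure(list(n = n, len = n, kind = "sign_flip"),
            class = c("sign_flip_design", "design"))
}

#' Planar rotation design
#'
#' A finite subset `G*` of the (infinite) rotation group SO(2), used by the
#' subset-shift test.  The default statistic is the first coordinate; the
#' null asserts rotation invariance of the data distribution.
#'
#' @param d Dimension (only `d = 2` is implemented).
#' @param G_star A `transformation_set` of rotations.
#' @return An object of class `"rotation_design"`.
#' @export
rotation_design <- function(d = 2L, G_star) {
  d <- as.integer(d)
  if (d != 2L) stop("only d = 2 rotation designs are implemented")
  stopifnot(inherits(G_star, "transformation_set"), G_star$kind == "rotation")
  structure(list(d = d, len = d, G_star = G_star, kind = "rotation"),
            class = c("rotation_design", "design"))
}

#' Difference-of-sums two-sample statistic
#'
#' `T(x) = sum(x[1:n]) - sum(x[(n+1):(2n)])` for a vector of even length
#' `2n` laid out cases-then-controls.
#'
#' @param x Numeric vector of even length.
#' @return The statistic value.
#' @export
two_sample_statistic <- function(x) {
  len <- length(x)
  if (len %% 2L != 0L) stop("two_sample_statistic requires an even-length vector")
  n <- len %/% 2L
  sum(x[seq_len(n)]) - sum(x[n + seq_len(n)])
}

#' Default test statistic of a design
#' @param design A design object.
#' @return A function mapping a data vector to a real number.
#' @export
design_statistic <- function(design) {
  if (inherits(design, "two_sample_design")) return(two_sample_statistic)
  if (inherits(design, "sign_flip_design")) return(function(x) sum(x))
  if (inherits(design, "rotation_design")) return(function(x) x[[1L]])
  stop("unknown design")
}

#' Transformation group of a design
#' @param design A design object.
#' @return A `group_spec` (or the stored `G*` set for rotation designs).
#' @export
design_group <- function(design) {
  if (inherits(design, "two_sample_design")) return(sym_group(design$len))
  if (inherits(design, "sign_flip_design")) return(signflip_group(design$n))
  if (inherits(design, "rotation_design")) return(design$G_star)
  stop("unknown design")
}

#' Equivalence-class label of a permutation under the two-sample design
#'
#' The label is the sorted set of original indices that `g` places into
#' the case positions `1..n`.  Two permutations yield equal two-sample
#' statistics for generic continuous data exactly when their labels agree;
#' the labels therefore index the partition into `choose(2n, n)` classes of
#' size `n! n!` on which the statistic is constant.
#'
#' @param g An index permutation of `2n` items.
#' @param design A `two_sample_design`.
#' @return Sorted integer vector of length `n` (the class label).
#' @export
class_of_permutation <- function(g, design) {
  stopifnot(inherits(design, "two_sample_design"),
            g$kind == "index_permutation",
            transformation_dim(g) == design$len)
  sort(g$payload[seq_len(design$n)])
}

#' All class labels of a two-sample design
#'
#' Enumerates the `choose(2n, n)` case-subsets, identity's class
#' (`1..n`) first.
#'
#' @param design A `two_sample_design`.
#' @return A list of sorted integer vectors.
#' @export
class_labels <- function(design) {
  stopifnot(inherits(design, "two_sample_design"))
  subs <- utils::combn(design$len, design$n, simplify = FALSE)
  id_lab <- seq_len(design$n)
  is_id <- vapply(subs, function(s) identical(s, id_lab), logical(1))
  c(subs[is_id], subs[!is_id])
}

#' Canonical class representative for a case-subset
#'
#' The permutation that moves the chosen case-subset into positions
#' `1..n`, preserving relative order within cases and within controls.
#' Any member of the class would do; the canonical choice is for
#' reproducibility only.
#'
#' @param design A `two_sample_design`.
#' @param case_subset Sorted integer vector of length `n` (original indices).
#' @return An index permutation transformation.
#' @export
class_representative <- function(design, case_subset) {
  stopifnot(inherits(design, "two_sample_design"),
            length(case_subset) == design$n)
  case_subset <- sort(as.integer(case_subset))
  perm_transform(c(case_subset, setdiff(seq_len(design$len), case_subset)))
}

#' Draw class representatives for the two-sample design
#'
#' Returns a Definition-2 style vector `(id, h_{i_2}, ..., h_{i_w})` whose
#' random entries are canonical representatives of equivalence classes:
#' drawn with replacement from all `m` class representatives, or without
#' replacement from the `m - 1` non-identity classes (then `w <= m`).
#' Under without-replacement sampling the resulting test is exact for all
#' `alpha` in `{0/w, ..., (w-1)/w}` when the data are continuous.
#'
#' @param design A `two_sample_design`.
#' @param w Total number of transformations, identity included.
#' @param scheme `"with_replacement"` or `"without_replacement"`.
#' @param seed Optional integer seed.
#' @return A `"drawn_transformations"` object (scheme prefixed
#'   `"representatives_"`).
#' @export
representatives <- function(design, w,
                            scheme = c("with_replacement", "without_replacement"),
                            seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(design, "two_sample_design"))
  w <- as.integer(w)
  if (w < 1L) stop("w must be at least 1")
  m <- choose(design$len, design$n)
  if (scheme == "without_replacement" && w > m)
    stop("w = ", w, " exceeds the number of classes m = ", m,
         " under without-replacement sampling")
  labs <- class_labels(design)          # identity class first
  seed <- resolve_seed(seed)
  idx <- withr::with_seed(seed, {
    if (w == 1L) integer(0)
    else if (scheme == "with_replacement") sample.int(m, w - 1L, replace = TRUE)
    else sample(seq(2L, m), w - 1L)
  })
  draws <- c(list(identity_transformation("index_permutation", design$len)),
             lapply(labs[idx], class_representative, design = design))
  structure(list(transformations = draws,
                 scheme = paste0("representatives_", scheme), w = w,
                 seed_record = list(seed = seed, kind = RNGkind()[1L])),
            class = "drawn_transformations")
}

# case-subsets that swap exactly half the cases with half the controls
balanced_labels <- function(design) {
  n <- design$n
  half <- n %/% 2L
  case_half <- utils::combn(seq_len(n), half, simplify = FALSE)
  ctrl_half <- utils::combn(n + seq_len(n), half, simplify = FALSE)
  labs <- list()
  for (a in case_half) for (b in ctrl_half)
    labs[[length(labs) + 1L]] <- c(a, b)
  labs
}

#' Balanced permutations (a non-group negative control)
#'
#' Permutations that exchange exactly `n/2` original cases with `n/2`
#' original controls.  With `representatives = TRUE` (default) one
#' canonical class representative per balanced case-subset is returned
#' (`choose(n, n/2)^2` elements); with `representatives = FALSE` every
#' permutation whose case-subset is balanced is enumerated
#' (`choose(n, n/2)^2 * n! * n!` elements) — the balanced-permutation set
#' of the literature.  Neither set is a subgroup of the permutation
#' group, and running the plain rejection rule over it (plus the
#' identity) is anti-conservative; it exists here purely as a negative
#' control.
#'
#' @param design A `two_sample_design` with even `n`.
#' @param include_identity Prepend the identity (needed to even attempt a
#'   test over the set).
#' @param verify Run [verify_group()] on the result (small `n` only) so the
#'   certificate records `"verified_not_group"`.
#' @param representatives One canonical permutation per balanced
#'   case-subset, or the full set.
#' @return A `transformation_set`.
#' @export
balanced_permutation_set <- function(design, include_identity = FALSE,
                                     verify = FALSE, representatives = TRUE) {
  stopifnot(inherits(design, "two_sample_design"))
  n <- design$n
  if (n %% 2L != 0L) stop("balanced permutations require an even number of cases")
  labs <- balanced_labels(design)
  if (representatives) {
    elems <- lapply(labs, class_representative, design = design)
  } else {
    case_orders <- all_permutations(n)
    elems <- list()
    for (lab in labs) {
      comp <- setdiff(seq_len(design$len), lab)
      for (po in case_orders) for (qo in case_orders)
        elems[[length(elems) + 1L]] <- perm_transform(c(lab[po], comp[qo]))
    }
  }
  if (include_identity)
    elems <- c(list(identity_transformation("index_permutation", design$len)),
               elems)
  S <- transformation_set(elems)
  if (verify) S <- verify_group(S)
  S
}

#' Random finite subset of the planar rotation group
#'
#' Builds `G*` as rotations by angles `theta_1 = 0` (the identity, included
#' for convenience) and `size - 1` further angles iid uniform on
#' `[0, 2*pi)`.
#'
#' @param d Dimension; only 2 is implemented.
#' @param size Number of rotations including the identity.
#' @param seed Optional integer seed.
#' @return A `rotation_design` whose `G_star` holds the sampled rotations
#'   (angles in attribute `"angles"`).
#' @export
rotation_subset <- function(d = 2L, size, seed = NULL) {
  if (d != 2L) stop("only d = 2 rotation subsets are implemented")
  size <- as.integer(size)
  stopifnot(size >= 1L)
  seed <- resolve_seed(seed)
  angles <- c(0, withr::with_seed(seed, stats::runif(size - 1L, 0, 2 * pi)))
  rot <- function(th) rotation_transform(matrix(c(cos(th), sin(th),
                                                  -sin(th), cos(th)), 2L, 2L))
  G_star <- transformation_set(lapply(angles, rot))
  attr(G_star, "angles") <- angles
  rotation_design(2L, G_star)
}
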