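# Synthetic-data generation and the Monte Carlo harness.  Every level /
# exactness / uniformity claim made by the test procedures has a harness
# configuration here; the acceptance suite asserts the claims against
# 3-standard-error binomial bands derived from the chosen replicate count.
#
# Two engines compute type-I error estimates: a "reference" engine that
# loops over the object-level test functions (slow, used as the oracle at
# small replicate counts), and a "vectorized" engine whose per-design
# kernels evaluate thousands of replicates with matrix operations.  The
# two are checked against each other on identical inputs in the test
# suite; the vectorized engine is what makes 20k-50k-replicate experiments
# affordable.

#' Null data models
#'
#' Families:
#' * `gaussian`: iid standard normal — exchangeable and symmetric about 0,
#'   valid for all designs.
#' * `exponential_centered`: iid `Exp(rate)` minus its mean — exchangeable
#'   (two-sample designs); *not* symmetric about 0, so not a sign-flip null.
#' * `bernoulli_signed`: iid uniform on `{-1, +1}` — symmetric and
#'   tie-prone.
#' * `integer_ties`: iid uniform on a small integer support
#'   (default `0:2`) — exchangeable and heavily tied; use a symmetric
#'   support such as `-1:1` for sign-flip designs.
#'
#' @param family Model family.
#' @param n Vector length (use `2n` for a two-sample design).
#' @param support Integer support for `integer_ties`.
#' @param rate Rate for `exponential_centered`.
#' @return An object of class `"null_model"`.
#' @export
null_model <- function(family = c("gaussian", "exponential_centered",
                                  "bernoulli_signed", "integer_ties"),
                       n, support = 0:2, rate = 1) {
  family <- match.arg(family)
  n <- as.integer(n)
  stopifnot(n >= 1L)
  structure(list(family = family, n = n, support = as.numeric(support),
                 rate = rate),
            class = "null_model")
}

# reps x n matrix of null draws (consumes the current RNG stream).
null_matrix <- function(model, reps) {
  n <- model$n
  switch(model$family,
    gaussian = matrix(stats::rnorm(reps * n), reps, n),
    exponential_centered =
      matrix(stats::rexp(reps * n, model$rate) - 1 / model$rate, reps, n),
    bernoulli_signed =
      matrix(sample(c(-1, 1), reps * n, replace = TRUE), reps, n),
    integer_ties =
      matrix(sample(model$support, reps * n, replace = TRUE), reps, n))
}

#' Draw one dataset from a null model
#'
#' @param model A `"null_model"`.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `model$n`.
#' @export
generate_null <- function(model, seed = NULL) {
  stopifnot(inherits(model, "null_model"))
  if (is.null(seed)) return(as.numeric(null_matrix(model, 1L)))
  withr::with_seed(as.integer(seed), as.numeric(null_matrix(model, 1L)))
}

#' Draw one dataset under a location-shift alternative
#'
#' Two-sample layouts (`n` even, interpreted as `2k` with cases first) add
#' `shift` to the case positions; sign-flip layouts add `shift` to every
#' entry.
#'
#' @param model A `"null_model"`.
#' @param shift Nonnegative location shift.
#' @param design Either `"sign_flip"` or `"two_sample"`.
#' @param seed Optional integer seed.
#' @return Numeric vector.
#' @export
generate_alternative <- function(model, shift,
                                 design = c("sign_flip", "two_sample"),
                                 seed = NULL) {
  design <- match.arg(design)
  stopifnot(shift >= 0)
  x <- generate_null(model, seed)
  if (design == "sign_flip") x + shift
  else {
    if (model$n %% 2L != 0L) stop("two-sample alternatives need even n")
    x[seq_len(model$n %/% 2L)] <- x[seq_len(model$n %/% 2L)] + shift
    x
  }
}

# ---- test configurations --------------------------------------------------

#' Harness test configurations
#'
#' Declarative descriptions of a test procedure for [estimate_type1()]:
#' which design, which variant (full-group / random draws /
#' representatives / subset-shift / balanced negative control), and the
#' sampling parameters.  Transformations are redrawn fresh on every
#' replicate, which is what the unconditional level statements average
#' over.
#'
#' @param design A design object.
#' @param randomized Use the boundary-randomized (exact) variant.
#' @param w Total transformations per replicate, identity included.
#' @param scheme Sampling scheme for the random draws.
#' @param size Size of the rotation subset `G*` (redrawn per replicate).
#' @param acknowledge_nongroup Required opt-in for the balanced
#'   (non-group) negative control.
#' @return An object of class `"test_config"`.
#' @export
config_full_group <- function(design, randomized = FALSE) {
  structure(list(type = "full_group", design = design, randomized = randomized),
            class = "test_config")
}

#' @rdname config_full_group
#' @export
config_random <- function(design, w,
                          scheme = c("with_replacement", "without_replacement"),
                          randomized = FALSE) {
  scheme <- match.arg(scheme)
  structure(list(type = "random", design = design, w = as.integer(w),
                 scheme = scheme, randomized = randomized),
            class = "test_config")
}

#' @rdname config_full_group
#' @export
config_representative <- function(design, w,
                                  scheme = c("without_replacement",
                                             "with_replacement")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(design, "two_sample_design"))
  structure(list(type = "representative", design = design, w = as.integer(w),
                 scheme = scheme),
            class = "test_config")
}

#' @rdname config_full_group
#' @export
config_subset_shift <- function(design = NULL, size = 12L) {
  structure(list(type = "subset_shift", design = design,
                 size = as.integer(size)),
            class = "test_config")
}

#' @rdname config_full_group
#' @export
config_balanced <- function(design, acknowledge_nongroup = FALSE) {
  stopifnot(inherits(design, "two_sample_design"))
  if (!acknowledge_nongroup)
    stop("the balanced-permutation configuration runs a test over a ",
         "NON-GROUP set and is anti-conservative by construction; pass ",
         "acknowledge_nongroup = TRUE to run it as a negative control")
  structure(list(type = "balanced", design = design,
                 acknowledge_nongroup = TRUE),
            class = "test_config")
}

new_simulation_result <- function(reps, rejections, config_echo, seed) {
  est <- rejections / reps
  se <- sqrt(est * (1 - est) / reps)
  structure(list(reps = reps, rejections = rejections, estimate = est,
                 se = se, ci95 = c(est - 1.96 * se, est + 1.96 * se),
                 config_echo = config_echo, seed = seed),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("simulation_result:", x$rejections, "/", x$reps,
      "rejections; estimate =", format(x$estimate),
      "(se", format(x$se), ")\n")
  invisible(x)
}

# ---- vectorized kernels ---------------------------------------------------

# k-th smallest per row
row_kth <- function(mat, k) {
  apply(mat, 1L, function(r) sort.int(r, partial = k)[k])
}

# Matrix of all 2^n sign patterns, identity (all +1) first.
all_sign_patterns <- function(n) {
  SM <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  dimnames(SM) <- NULL
  SM  # first row of expand.grid is all +1 already
}

# +-1 class indicator matrix for two-sample class labels (identity first).
class_sign_matrix <- function(labels, len) {
  V <- matrix(-1, length(labels), len)
  for (i in seq_along(labels)) V[i, labels[[i]]] <- 1
  V
}

# Decision rule applied rowwise to a matrix of statistics whose N "true"
# columns may be represented by ncol(stats) columns each of multiplicity
# mult (equal-size equivalence classes: the full sorted vector is the
# sorted class vector with each value repeated mult times).
kernel_decide <- function(stats, obs, alpha, mult = 1L, randomized = FALSE) {
  N <- ncol(stats) * mult
  k <- rank_threshold_index(alpha, N)
  kc <- ceiling(k / mult)
  Tk <- row_kth(stats, kc)
  rej <- obs > Tk
  if (randomized) {
    Mp <- mult * rowSums(stats > Tk)
    M0 <- mult * rowSums(stats == Tk)
    a <- pmin(pmax((alpha * N - Mp) / M0, 0), 1)
    U <- stats::runif(length(obs))
    rej <- rej | (obs == Tk & U < a)
  }
  rej
}

# Build the per-replicate statistics matrix for a configuration.  Returns
# list(stats, obs, mult).  Consumes the current RNG stream.
kernel_stats <- function(config, model, reps, shift = 0) {
  design <- config$design
  if (config$type %in% c("full_group", "random") &&
      inherits(design, "sign_flip_design")) {
    n <- design$n
    stopifnot(model$n == n)
    X <- null_matrix(model, reps)
    if (shift != 0) X <- X + shift
    if (config$type == "full_group") {
      SM <- all_sign_patterns(n)
      stats <- X %*% t(SM)
      return(list(stats = stats, obs = stats[, 1L], mult = 1L))
    }
    w <- config$w
    stats <- matrix(0, reps, w)
    stats[, 1L] <- rowSums(X)
    if (config$scheme == "with_replacement") {
      for (j in seq_len(w - 1L)) {
        S <- matrix(sample(c(-1, 1), reps * n, replace = TRUE), reps, n)
        stats[, j + 1L] <- rowSums(X * S)
      }
    } else {
      Ng <- 2^n
      if (w > Ng) stop("w exceeds #G")
      # distinct non-identity sign patterns per replicate, via integer codes
      codes <- vapply(seq_len(reps),
                      function(i) sample.int(Ng - 1L, w - 1L), integer(w - 1L))
      codes <- if (w == 2L) matrix(codes, 1L) else codes   # (w-1) x reps
      for (j in seq_len(w - 1L)) {
        cj <- codes[j, ]
        S <- matrix(1, reps, n)
        for (b in seq_len(n))
          S[, b] <- 1 - 2 * ((cj %/% 2^(b - 1L)) %% 2L)
        stats[, j + 1L] <- rowSums(X * S)
      }
    }
    return(list(stats = stats, obs = stats[, 1L], mult = 1L))
  }
  if (inherits(design, "two_sample_design")) {
    n <- design$n
    stopifnot(model$n == design$len)
    X <- null_matrix(model, reps)
    if (shift != 0) X[, seq_len(n)] <- X[, seq_len(n)] + shift
    if (config$type == "full_group") {
      V <- class_sign_matrix(class_labels(design), design$len)
      CS <- X %*% t(V)
      return(list(stats = CS, obs = CS[, 1L],
                  mult = factorial(n)^2))
    }
    if (config$type == "representative") {
      V <- class_sign_matrix(class_labels(design), design$len)
      CS <- X %*% t(V)
      m <- ncol(CS)
      w <- config$w
      idx <- if (config$scheme == "without_replacement") {
        if (w > m) stop("w exceeds m")
        vapply(seq_len(reps), function(i) sample(seq(2L, m), w - 1L),
               integer(w - 1L))
      } else {
        vapply(seq_len(reps), function(i) sample.int(m, w - 1L, replace = TRUE),
               integer(w - 1L))
      }
      idx <- if (w == 2L) matrix(idx, 1L) else idx          # (w-1) x reps
      picked <- matrix(CS[cbind(rep(seq_len(reps), each = w - 1L),
                                as.vector(idx))],
                       reps, w - 1L, byrow = TRUE)
      stats <- cbind(CS[, 1L], picked)
      return(list(stats = stats, obs = stats[, 1L], mult = 1L))
    }
    if (config$type == "balanced") {
      # Full balanced set: every balanced class contributes n!n! equal
      # statistic values; the identity contributes one more.  The decision
      # "obs > T^{(k)}" is equivalent to "at least k of the N values lie
      # strictly below obs".
      V <- class_sign_matrix(balanced_labels(design), design$len)
      B <- X %*% t(V)
      obs <- rowSums(X[, seq_len(n), drop = FALSE]) -
        rowSums(X[, n + seq_len(n), drop = FALSE])
      multb <- factorial(n)^2
      decide <- function(stats, obs, alpha) {
        N <- ncol(stats) * multb + 1
        k <- rank_threshold_index(alpha, N)
        (multb * rowSums(stats < obs)) >= k
      }
      return(list(stats = B, obs = obs, mult = 1L, decide = decide))
    }
  }
  if (config$type == "subset_shift") {
    size <- config$size
    X <- null_matrix(model, reps)              # rotation-invariant null: N(0, I_2)
    stopifnot(model$n == 2L)
    theta <- cbind(0, matrix(stats::runif(reps * (size - 1L), 0, 2 * pi),
                             reps, size - 1L))
    h <- sample.int(size, reps, replace = TRUE)
    th_h <- theta[cbind(seq_len(reps), h)]
    delta <- theta - th_h
    stats <- cos(delta) * X[, 1L] - sin(delta) * X[, 2L]
    return(list(stats = stats, obs = X[, 1L], mult = 1L))
  }
  stop("no vectorized kernel for this configuration")
}

# One reference replicate through the object API (oracle engine).
reference_rep <- function(config, x, alpha) {
  design <- config$design
  stat <- design_statistic(design)
  if (config$type == "full_group") {
    G <- design_group(design)
    r <- if (config$randomized) hoeffding_randomized_test(x, G, stat, alpha)
         else full_group_test(x, G, stat, alpha)
    return(r$reject)
  }
  if (config$type == "random") {
    drawn <- draw_transformations(design_group(design), config$w, config$scheme)
    r <- if (config$randomized) randomized_random_perm_test(x, drawn, stat, alpha)
         else random_perm_test(x, drawn, stat, alpha)
    return(r$reject)
  }
  if (config$type == "representative") {
    return(representative_random_test(x, design, config$w, config$scheme,
                                      alpha)$reject)
  }
  if (config$type == "balanced") {
    S <- balanced_permutation_set(design, include_identity = TRUE,
                                  representatives = FALSE)
    r <- suppressWarnings(full_group_test(x, S, stat, alpha,
                                          allow_nongroup = TRUE))
    return(r$reject)
  }
  if (config$type == "subset_shift") {
    rd <- rotation_subset(2L, config$size)
    return(subset_shift_test(x, rd$G_star, design_statistic(rd), alpha)$reject)
  }
  stop("unknown configuration type")
}

#' Estimate the type-I error rate of a configured test
#'
#' Runs the configured test on `reps` fresh null datasets (with fresh
#' transformation draws on every replicate where applicable) and returns
#' the empirical rejection rate with its binomial standard error and 95%
#' confidence interval.  Reproducible from `seed`.
#'
#' @param config A `"test_config"`.
#' @param model A `"null_model"` matching the design's data length.
#' @param reps Number of replicates.
#' @param alpha Nominal level (may be a vector; the vectorized engine
#'   reuses one set of replicates across the grid, the reference engine
#'   redraws).
#' @param seed Integer seed.
#' @param engine `"vectorized"` (fast kernels), `"reference"` (object-API
#'   loop, the oracle), or `"auto"`.
#' @return A `"simulation_result"`, or a list of them when `alpha` is a
#'   vector.
#' @export
estimate_type1 <- function(config, model, reps, alpha, seed = NULL,
                           engine = c("auto", "vectorized", "reference")) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "test_config"), inherits(model, "null_model"),
            reps >= 1)
  seed <- resolve_seed(seed)
  echo <- list(config = unclass(config)[setdiff(names(config), "design")],
               design = class(config$design)[1L],
               model = unclass(model), reps = reps)
  if (engine == "auto") engine <- "vectorized"
  if (engine == "vectorized") {
    km <- withr::with_seed(seed, kernel_stats(config, model, reps))
    out <- lapply(alpha, function(a) {
      rej <- withr::with_seed(derive_seed(seed, paste0("decide-", a)), {
        if (!is.null(km$decide)) km$decide(km$stats, km$obs, a)
        else kernel_decide(km$stats, km$obs, a, km$mult,
                           randomized = isTRUE(config$randomized))
      })
      new_simulation_result(reps, sum(rej), c(echo, alpha = a), seed)
    })
  } else {
    out <- lapply(alpha, function(a) {
      rej <- withr::with_seed(derive_seed(seed, paste0("ref-", a)), {
        vapply(seq_len(reps), function(i)
          reference_rep(config, generate_null(model), a), logical(1))
      })
      new_simulation_result(reps, sum(rej), c(echo, alpha = a), seed)
    })
  }
  if (length(alpha) == 1L) out[[1L]] else out
}

#' Estimate power under a location-shift alternative
#'
#' Same harness as [estimate_type1()] but data are drawn from
#' [generate_alternative()]'s shift model (cases shifted for two-sample
#' designs; all entries shifted for sign-flip designs).
#'
#' @inheritParams estimate_type1
#' @param shift Nonnegative location shift.
#' @return A `"simulation_result"`.
#' @export
estimate_power <- function(config, model, shift, reps, alpha, seed = NULL) {
  stopifnot(shift >= 0, length(alpha) == 1L)
  seed <- resolve_seed(seed)
  km <- withr::with_seed(seed, kernel_stats(config, model, reps, shift = shift))
  rej <- withr::with_seed(derive_seed(seed, paste0("decide-", alpha)),
    kernel_decide(km$stats, km$obs, alpha, km$mult,
                  randomized = isTRUE(config$randomized)))
  new_simulation_result(reps, sum(rej),
                        list(design = class(config$design)[1L], shift = shift,
                             alpha = alpha, model = unclass(model)),
                        seed)
}

# ---- p-value simulation kernels ------------------------------------------

# For sign-flip models: per replicate, draw `w` random sign patterns
# (with or without replacement from the group minus the identity for the
# without-replacement scheme) and return the counts of draws with
# statistic >, >=, = relative to the observed sum.  Consumes the RNG.
signflip_pvalue_counts <- function(model, reps, w,
                                   scheme = c("with_replacement",
                                              "without_replacement")) {
  scheme <- match.arg(scheme)
  n <- model$n
  X <- null_matrix(model, reps)
  obs <- rowSums(X)
  gt <- integer(reps); ge <- integer(reps)
  if (scheme == "with_replacement") {
    for (j in seq_len(w)) {
      S <- matrix(sample(c(-1, 1), reps * n, replace = TRUE), reps, n)
      s <- rowSums(X * S)
      gt <- gt + (s > obs)
      ge <- ge + (s >= obs)
    }
  } else {
    Ng <- 2^n
    if (w > Ng - 1L) stop("w exceeds #G - 1")
    codes <- vapply(seq_len(reps), function(i) sample.int(Ng - 1L, w),
                    integer(w))
    codes <- if (w == 1L) matrix(codes, 1L) else codes
    for (j in seq_len(w)) {
      cj <- codes[j, ]
      S <- matrix(1, reps, n)
      for (b in seq_len(n))
        S[, b] <- 1 - 2 * ((cj %/% 2^(b - 1L)) %% 2L)
      s <- rowSums(X * S)
      gt <- gt + (s > obs)
      ge <- ge + (s >= obs)
    }
  }
  list(gt = gt, ge = ge, eq = ge - gt, w = w)
}

#' Simulate the p-value constructions under the null
#'
#' For each replicate draws a fresh sign-flip null dataset and `w` random
#' sign patterns (identity *not* among them), then computes the naive
#' `B/w`, the plus-one `(B+1)/(w+1)`, the randomized `p'` over the
#' identity-adjoined vector of `w + 1` transformations (fresh `u` per
#' replicate), and its upper bound.
#'
#' @param model Sign-flip-compatible `"null_model"` (symmetric about 0).
#' @param reps Replicates.
#' @param w Number of random draws (identity excluded).
#' @param scheme Sampling scheme for the draws.
#' @param seed Integer seed.
#' @return A data.frame with one row per replicate and columns `B`,
#'   `p_naive`, `p_plus_one`, `p_randomized`, `p_upper`, `u`.
#' @export
simulate_pvalues <- function(model, reps, w,
                             scheme = c("with_replacement",
                                        "without_replacement"),
                             seed = NULL) {
  scheme <- match.arg(scheme)
  seed <- resolve_seed(seed)
  cnt <- withr::with_seed(seed, signflip_pvalue_counts(model, reps, w, scheme))
  u <- withr::with_seed(derive_seed(seed, "u"), stats::runif(reps))
  # identity-adjoined vector: w + 1 transformations, equality count gains 1
  w1 <- w + 1L
  data.frame(B = cnt$ge,
             p_naive = cnt$ge / w,
             p_plus_one = (cnt$ge + 1) / (w + 1),
             p_randomized = (cnt$gt + u * (cnt$eq + 1)) / w1,
             p_upper = (cnt$ge + 1) / w1,
             u = u)
}

#' Exact probability that the naive p-value is zero
#'
#' Finite-population oracle for `P(B = 0)` under a continuous sign-flip
#' null with `w` with-replacement draws from a group of `N` elements whose
#' statistic values are distinct on the orbit: the rank of the observed
#' statistic is uniform, so `P(B = 0) = N^{-(w+1)} * sum_{j=0}^{N-1} j^w`.
#'
#' @param N Group size (e.g. `2^n` for sign flips).
#' @param w Number of random draws.
#' @return The exact probability.
#' @export
naive_zero_oracle <- function(N, w) {
  mean(((seq_len(N) - 1) / N)^w)
}

#' Demonstrate the anti-conservativeness of the naive p-value
#'
#' For each cutoff `c`, estimates `P(p_hat <= c)` and `P(p_tilde <= c)`
#' under a sign-flip null with `w` with-replacement draws.  The naive rate
#' exceeds `c` for small `c` (it converges to `P(B = 0) > 0` as `c` goes
#' to 0) while the plus-one rate never does.
#'
#' @param w Number of random draws.
#' @param c_grid Cutoffs.
#' @param model Sign-flip `"null_model"`.
#' @param reps Replicates.
#' @param seed Integer seed.
#' @return data.frame with columns `c`, `p_naive_rate`, `p_naive_se`,
#'   `p_plus_rate`, `p_plus_se`.
#' @export
phipson_smyth_demo <- function(w, c_grid, model, reps, seed = NULL) {
  stopifnot(w >= 2)
  sim <- simulate_pvalues(model, reps, w, "with_replacement", seed)
  rows <- lapply(c_grid, function(cc) {
    r1 <- mean(sim$p_naive <= cc)
    r2 <- mean(sim$p_plus_one <= cc)
    data.frame(c = cc,
               p_naive_rate = r1, p_naive_se = sqrt(r1 * (1 - r1) / reps),
               p_plus_rate = r2, p_plus_se = sqrt(r2 * (1 - r2) / reps))
  })
  do.call(rbind, rows)
}

#' Balanced-permutation negative control
#'
#' Runs, on the *same* null datasets, (a) the plain rejection rule over
#' the non-group balanced set plus the identity and (b) the honest
#' full-group permutation test, and reports both empirical type-I error
#' rates together with a one-sided binomial p-value against the
#' hypothesis that the balanced arm's rate is at most `alpha`.
#'
#' @param n Number of cases (even, at least 4).
#' @param alpha Nominal level.
#' @param reps Replicates.
#' @param seed Integer seed.
#' @param acknowledge_nongroup Must be `TRUE`; this deliberately runs a
#'   test whose level guarantee is void.
#' @return A list with `balanced` and `full_group` simulation results and
#'   `binom_p`, the one-sided binomial p-value for rate > alpha.
#' @export
balanced_demo <- function(n, alpha, reps, seed = NULL,
                          acknowledge_nongroup = FALSE) {
  if (!acknowledge_nongroup)
    stop("balanced_demo runs a NON-GROUP test as a negative control; ",
         "pass acknowledge_nongroup = TRUE to proceed")
  n <- as.integer(n)
  if (n %% 2L != 0L || n < 4L) stop("n must be even and at least 4")
  design <- two_sample_design(n)
  model <- null_model("gaussian", design$len)
  seed <- resolve_seed(seed)
  X <- withr::with_seed(seed, null_matrix(model, reps))
  # balanced arm: full balanced set (each balanced class has n!n! members)
  # plus the identity; reject iff at least k of the N values lie strictly
  # below the observed statistic.
  Vb <- class_sign_matrix(balanced_labels(design), design$len)
  Sb <- X %*% t(Vb)
  obs <- rowSums(X[, seq_len(n), drop = FALSE]) -
    rowSums(X[, n + seq_len(n), drop = FALSE])
  multb <- factorial(n)^2
  Nb <- ncol(Sb) * multb + 1
  kb <- rank_threshold_index(alpha, Nb)
  rej_b <- (multb * rowSums(Sb < obs)) >= kb
  # honest full-group arm on identical data
  Vf <- class_sign_matrix(class_labels(design), design$len)
  Sf <- X %*% t(Vf)
  rej_f <- kernel_decide(Sf, Sf[, 1L], alpha, mult = factorial(n)^2)
  bt <- stats::binom.test(sum(rej_b), reps, p = alpha, alternative = "greater")
  list(balanced = new_simulation_result(reps, sum(rej_b),
         list(arm = "balanced_nongroup", n = n, alpha = alpha), seed),
       full_group = new_simulation_result(reps, sum(rej_f),
         list(arm = "full_group", n = n, alpha = alpha), seed),
       binom_p = bt$p.value)
}
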