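# test procedures: rejection rules, thresholds, boundary randomization,
# oracle equivalences, invariance properties

test_that("full_group_test: never rejects at alpha = 0; sign-flip enumeration", {
  withr::with_seed(1, {
    for (i in 1:5) {
      x <- rnorm(4)
      expect_false(full_group_test(x, signflip_group(4), sum, 0)$reject)
    }
  })
  # n = 3, x = (1,2,3), alpha = 0.125: observed sum 6 is the unique max of
  # the 8 signed sums, k = 7, so the test rejects
  r <- full_group_test(c(1, 2, 3), signflip_group(3), sum, 0.125)
  expect_true(r$reject)
  expect_equal(r$k, 7)
  # at alpha = 0.12 (below 1/8) rejection is impossible
  expect_false(full_group_test(c(1, 2, 3), signflip_group(3), sum, 0.12)$reject)
})

test_that("two-sample full group: alpha below 1/m cannot reject", {
  # ceil(0.97 * 720) = 699 falls inside the top class of 36, so the
  # threshold is the maximum and strict rejection is impossible
  G6 <- materialize_group(sym_group(6))
  withr::with_seed(2, {
    for (i in 1:3) {
      x <- rnorm(6)
      r <- full_group_test(x, G6, two_sample_statistic, 0.03)
      expect_false(r$reject)
      expect_equal(r$k, 699)
    }
  })
})

test_that("uncertified sets are refused; override warns", {
  S <- balanced_permutation_set(two_sample_design(2), include_identity = TRUE)
  x <- fix_x(4, 7)
  expect_error(full_group_test(x, S, two_sample_statistic, 0.2), "verified group")
  expect_warning(full_group_test(x, S, two_sample_statistic, 0.2,
                                 allow_nongroup = TRUE), "NON-GROUP")
})

test_that("hoeffding boundary probability a follows the printed formula", {
  # continuous x, n = 5: #G = 32, k = 31, M+ = 1, M0 = 1 -> a = 0.6
  x <- c(5.1, 4.2, 3.3, 2.4, 1.5)
  r <- hoeffding_randomized_test(x, signflip_group(5), sum, 0.05, seed = 1)
  expect_equal(r$a, 0.6)
  expect_equal(r$m_plus, 1)
  expect_equal(r$m_zero, 1)
  # M+ = alpha * #G exactly -> a = 0: observed at the boundary never rejects
  # sign-flip n = 2, x = (1, 2): sums -3,-1,1,3; alpha = 0.25, k = 3,
  # threshold 1, M+ = 1 = alpha * 4, M0 = 1
  r2 <- hoeffding_randomized_test(c(-1, 2), signflip_group(2), sum, 0.25, seed = 2)
  expect_equal(r2$a, 0)
  expect_false(r2$reject)  # observed sum 1 equals the threshold; a = 0
})

test_that("random_perm_test contracts: w = 1, identity-first, monotonicity", {
  x <- fix_x(6, 9)
  d1 <- draw_transformations(signflip_group(6), 1, seed = 1)
  expect_false(random_perm_test(x, d1, sum, 0.3)$reject)
  # identity missing -> error
  bad <- draw_transformations(signflip_group(6), 5, seed = 2)
  bad$transformations <- bad$transformations[-1]
  expect_error(random_perm_test(x, bad, sum, 0.3), "identity")
  # monotone in alpha for fixed x and draws (strict rule)
  drawn <- draw_transformations(signflip_group(6), 12, seed = 3)
  dec <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.4, 0.6),
                function(a) random_perm_test(x, drawn, sum, a)$reject, logical(1))
  expect_true(all(dec == cummax(dec)))
})

test_that("oracle equivalence: w = #G without replacement == full group", {
  G <- materialize_group(signflip_group(4))
  withr::with_seed(5, {
    for (i in 1:20) {
      x <- rnorm(4)
      drawn <- draw_transformations(G, 16, "without_replacement")
      for (a in c(0.05, 0.1, 0.25, 0.5)) {
        expect_identical(random_perm_test(x, drawn, sum, a)$reject,
                         full_group_test(x, G, sum, a)$reject)
      }
    }
  })
})

test_that("representatives at w = m reproduce the full-group decision", {
  d <- two_sample_design(3)
  G6 <- materialize_group(sym_group(6))
  withr::with_seed(6, {
    for (i in 1:5) {
      x <- rnorm(6)
      for (a in c(0.05, 0.1, 0.3)) {
        rr <- representative_random_test(x, d, 20, "without_replacement", a)
        rf <- full_group_test(x, G6, two_sample_statistic, a)
        expect_identical(rr$reject, rf$reject)
      }
    }
  })
})

test_that("randomized random test: certain rejection when observed is unique max", {
  x <- c(9, 8, 7, 6, 5)   # observed sum far above any sign-flipped sum
  drawn <- draw_transformations(signflip_group(5), 10, seed = 4)
  r <- randomized_random_perm_test(x, drawn, sum, alpha = 0.1, seed = 1)
  expect_true(r$reject)
})

test_that("randomized test decision is equivalent to p' <= alpha (shared u)", {
  withr::with_seed(8, {
    for (i in 1:60) {
      n <- 5
      x <- sample(0:1, n, replace = TRUE)   # heavy ties
      drawn <- draw_transformations(signflip_group(n), 8)
      u <- runif(1)
      for (a in c(0.05, 0.125, 0.25, 0.5)) {
        rej <- randomized_random_perm_test(x, drawn, sum, a, u = u)$reject
        pp <- randomized_pvalue(x, drawn, sum, u)
        expect_identical(rej, pp <= a)
      }
    }
  })
})

test_that("threshold is invariant under every group element", {
  # pivotal fact of the level proof: T^(k)(gX) = T^(k)(X) for all g in G,
  # for an arbitrary statistic
  Tq <- function(x) x[1] * 2 + x[2]^2 - sin(x[3])
  for (G in list(materialize_group(signflip_group(4)),
                 materialize_group(sym_group(3)))) {
    n <- G$dim
    x <- fix_x(n, 33)
    Tstat <- if (n == 4) Tq else function(x) x[1] * 2 + x[2]^2 - sin(x[3])
    base <- full_group_test(x, G, Tstat, 0.2)$threshold_value
    for (g in G$elements) {
      gx <- apply_transformation(g, x)
      expect_equal(full_group_test(gx, G, Tstat, 0.2)$threshold_value, base)
    }
  }
})

test_that("tie order does not matter: shuffled inputs give identical decisions", {
  # only the counts M+/M0 enter the decision, so shuffling tied data
  # entries (which permutes the statistic multiset) leaves it unchanged
  withr::with_seed(44, {
    x <- sample(0:1, 6, replace = TRUE)
    G <- materialize_group(signflip_group(6))
    r0 <- full_group_test(x, G, sum, 0.2)
    for (i in 1:5) {
      Gp <- transformation_set(sample(G$elements), certificate = "verified_group")
      r1 <- full_group_test(x, Gp, sum, 0.2)
      expect_identical(r1$reject, r0$reject)
      expect_identical(r1$threshold_value, r0$threshold_value)
      expect_identical(r1$m_plus, r0$m_plus)
      expect_identical(r1$m_zero, r0$m_zero)
    }
  })
})

test_that("subset-shift over a true group equals the full-group test for all h", {
  G <- materialize_group(signflip_group(3))
  withr::with_seed(10, {
    for (i in 1:5) {
      x <- rnorm(3)
      for (a in c(0.1, 0.2, 0.3, 0.5)) {
        full <- full_group_test(x, G, sum, a)$reject
        for (h in 1:8) {
          expect_identical(subset_shift_test(x, G, sum, a, h_index = h)$reject,
                           full)
        }
      }
    }
  })
  # singleton G* (identity only) never rejects
  id_set <- transformation_set(list(identity_transformation("sign_flip", 3)))
  expect_false(subset_shift_test(c(1, 2, 3), id_set, sum, 0.5, seed = 1)$reject)
})

test_that("monte_carlo_test: w = 1 never rejects; B' is uniform on 1..w", {
  expect_false(monte_carlo_test(3, function() rnorm(1), identity, 1, 0.3,
                                seed = 1)$reject)
  # B' uniformity under the null, via direct simulation of the defining
  # counts (fresh observed value and fresh Monte Carlo sample each rep)
  w <- 20; reps <- 4000
  Bp <- withr::with_seed(12, {
    S <- matrix(rnorm(reps * w), reps, w)
    rowSums(S >= S[, 1])
  })
  expect_gt(stats::chisq.test(tabulate(Bp, w))$p.value, 0.005)
  # and the test function itself is exact at moderate reps
  rej <- withr::with_seed(13, {
    vapply(seq_len(2000), function(i)
      monte_carlo_test(rnorm(1), function() rnorm(1), identity, 20, 0.1)$reject,
      logical(1))
  })
  expect_rate_equals(mean(rej), 0.1, 2000)
})

test_that("vectorized decision kernel agrees with the object-level rule", {
  # dual route: same statistics, same alpha -> identical strict decisions
  withr::with_seed(21, {
    for (i in 1:50) {
      x <- rnorm(6)
      drawn <- draw_transformations(signflip_group(6), 12)
      stats <- vapply(drawn$transformations,
                      function(g) sum(apply_transformation(g, x)), numeric(1))
      for (a in c(0.05, 0.1, 0.25)) {
        kd <- permexact:::kernel_decide(matrix(stats, 1), stats[1], a)
        expect_identical(as.logical(kd),
                         random_perm_test(x, drawn, sum, a)$reject)
      }
    }
  })
})

test_that("type-I error stays at or below alpha across designs and nulls", {
  reps <- 10000
  grid <- c(0.01, 0.05, 0.1, 0.2)
  cases <- list(
    list(cfg = config_full_group(sign_flip_design(5)),
         mod = null_model("gaussian", 5)),
    list(cfg = config_full_group(sign_flip_design(5)),
         mod = null_model("bernoulli_signed", 5)),
    list(cfg = config_random(sign_flip_design(8), 20),
         mod = null_model("integer_ties", 8, support = -1:1)),
    list(cfg = config_full_group(two_sample_design(3)),
         mod = null_model("integer_ties", 6)),
    list(cfg = config_full_group(two_sample_design(3)),
         mod = null_model("exponential_centered", 6)))
  for (cs in cases) {
    res <- estimate_type1(cs$cfg, cs$mod, reps, grid, seed = 77)
    for (j in seq_along(grid))
      expect_rate_at_most(res[[j]]$estimate, grid[j], reps)
  }
})
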