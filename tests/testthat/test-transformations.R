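# transformation algebra, group verification, orbits, random draws

test_that("constructors validate payloads", {
  expect_error(perm_transform(c(1, 1, 3)), "exactly once")
  expect_error(sign_transform(c(1, 0)), "-1 or \\+1")
  expect_error(rotation_transform(matrix(c(1, 0, 0, 2), 2)), "orthogonal")
  # reflection: orthogonal but det -1
  expect_error(rotation_transform(matrix(c(0, 1, 1, 0), 2)), "determinant")
  th <- 0.7
  expect_silent(rotation_transform(matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)))
})

test_that("composition and inverse follow the documented convention", {
  # action (gx)[i] = x[p[i]]; composition payload q = p_h[p_g]
  g <- perm_transform(c(2, 3, 1))
  h <- perm_transform(c(3, 1, 2))
  expect_equal(compose(g, h)$payload, 1:3)      # h = g^{-1}
  expect_equal(inverse(g)$payload, c(3L, 1L, 2L))
  id <- identity_transformation("index_permutation", 3)
  expect_equal(compose(id, h)$payload, h$payload)
  expect_equal(compose(sign_transform(c(1, -1, 1)),
                       sign_transform(c(-1, -1, 1)))$payload, c(-1, 1, 1))
  expect_error(compose(g, sign_transform(c(1, 1, 1))), "different kinds")
  expect_error(compose(g, perm_transform(1:4)), "dimensions")
})

test_that("round trip: apply(compose(g,h), x) == apply(g, apply(h, x))", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      n <- sample(3:7, 1)
      x <- rnorm(n)
      g <- perm_transform(sample(n)); h <- perm_transform(sample(n))
      expect_equal(apply_transformation(compose(g, h), x),
                   apply_transformation(g, apply_transformation(h, x)))
      s <- sign_transform(sample(c(-1, 1), n, TRUE))
      t2 <- sign_transform(sample(c(-1, 1), n, TRUE))
      expect_equal(apply_transformation(compose(s, t2), x),
                   apply_transformation(s, apply_transformation(t2, x)))
      expect_true(is_identity_transformation(compose(inverse(g), g)))
      expect_true(is_identity_transformation(compose(s, inverse(s))))
    }
  })
})

test_that("verify_group certifies true groups and rejects non-groups", {
  S3 <- transformation_set(materialize_group(sym_group(3))$elements)
  expect_equal(verify_group(S3)$group_certificate, "verified_group")
  pair <- transformation_set(list(identity_transformation("index_permutation", 3),
                                  perm_transform(c(2, 1, 3))))
  expect_equal(verify_group(pair)$group_certificate, "verified_group")
  bal <- balanced_permutation_set(two_sample_design(2), include_identity = TRUE,
                                  verify = TRUE)
  expect_equal(bal$group_certificate, "verified_not_group")
  expect_equal(attr(bal, "violation"), "closure_violation")
  expect_length(attr(bal, "witness"), 2)
  # the witness pair really does compose outside the set
  keys <- vapply(bal$elements, permexact:::transformation_key, character(1))
  w <- attr(bal, "witness")
  comp <- compose(bal$elements[[w[1]]], bal$elements[[w[2]]])
  expect_false(permexact:::transformation_key(comp) %in% keys)
  noid <- transformation_set(list(perm_transform(c(2, 1))))
  expect_equal(verify_group(noid)$group_certificate, "verified_not_group")
  expect_equal(attr(verify_group(noid), "violation"), "missing_identity")
  expect_error(verify_group(S3, cap = 2), "cap")
})

test_that("right-coset invariance Gg = G holds for verified groups", {
  for (G in list(materialize_group(signflip_group(3)),
                 materialize_group(sym_group(3)))) {
    keys <- sort(vapply(G$elements, permexact:::transformation_key, character(1)))
    for (g in G$elements) {
      ckeys <- sort(vapply(G$elements,
                           function(a) permexact:::transformation_key(compose(a, g)),
                           character(1)))
      expect_identical(ckeys, keys)
    }
  }
})

test_that("orbit enumerates distinct images", {
  x <- c(1, 2)
  id_only <- transformation_set(list(identity_transformation("index_permutation", 2)))
  expect_length(orbit(x, id_only), 1)
  S2 <- transformation_set(materialize_group(sym_group(2))$elements)
  expect_length(orbit(x, S2), 2)
  signs <- materialize_group(signflip_group(2))
  expect_length(orbit(x, signs), 4)
  expect_length(orbit(c(0, 0), signs), 1)   # degenerate point: orbit collapses
})

test_that("draw_transformations honours Definition-2 structure", {
  d1 <- draw_transformations(signflip_group(5), 1, "with_replacement", seed = 1)
  expect_length(d1$transformations, 1)
  expect_true(is_identity_transformation(d1$transformations[[1]]))
  # exhaustion: w = #G without replacement yields each element exactly once
  G <- materialize_group(signflip_group(3))
  dall <- draw_transformations(G, 8, "without_replacement", seed = 2)
  keys <- vapply(dall$transformations, permexact:::transformation_key, character(1))
  expect_setequal(keys, vapply(G$elements, permexact:::transformation_key, character(1)))
  expect_error(draw_transformations(G, 9, "without_replacement"), "exceeds")
  # no duplicates / no identity after position 1, implicit-group route
  dwo <- draw_transformations(signflip_group(10), 40, "without_replacement", seed = 3)
  k2 <- vapply(dwo$transformations, permexact:::transformation_key, character(1))
  expect_false(anyDuplicated(k2) > 0)
  expect_false(any(vapply(dwo$transformations[-1], is_identity_transformation,
                          logical(1))))
  # bit-reproducibility from the seed
  da <- draw_transformations(sym_group(6), 25, "with_replacement", seed = 42)
  db <- draw_transformations(sym_group(6), 25, "with_replacement", seed = 42)
  expect_identical(lapply(da$transformations, `[[`, "payload"),
                   lapply(db$transformations, `[[`, "payload"))
})

test_that("with-replacement draws are uniform on the group", {
  # explicit-set route: one long draw from S_3
  G <- materialize_group(sym_group(3))
  d <- draw_transformations(G, 60001, "with_replacement", seed = 7)
  keys <- vapply(d$transformations[-1], permexact:::transformation_key, character(1))
  freq <- table(keys)
  expect_length(freq, 6)
  expect_true(all(abs(freq / 60000 - 1 / 6) <= band3se(1 / 6, 60000)))
  # implicit-group route (uniform shuffle construction)
  d2 <- draw_transformations(sym_group(3), 12001, "with_replacement", seed = 8)
  k2 <- vapply(d2$transformations[-1], permexact:::transformation_key, character(1))
  f2 <- table(k2)
  expect_length(f2, 6)
  expect_true(all(abs(f2 / 12000 - 1 / 6) <= band3se(1 / 6, 12000)))
})
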