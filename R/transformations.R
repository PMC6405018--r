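# Transformations, transformation sets and random draws from groups.
#
# A transformation is one invertible map on data vectors: an index
# permutation, a sign-flip vector, or a planar rotation matrix.  Finite
# collections of transformations carry a certificate stating whether the
# group axioms (identity, inverses, closure) have been verified; the tests
# in perm-tests.R refuse uncertified sets because the level guarantee of a
# permutation test rests entirely on the group structure (Gg = G).

ROTATION_TOL <- 1e-10

#' Create a transformation
#'
#' Constructs a single invertible map on data vectors.  Three kinds are
#' supported: `index_permutation` (payload: a permutation of `1:n`, acting
#' as `(gx)[i] = x[p[i]]`), `sign_flip` (payload: a vector in `{-1, +1}^n`,
#' acting elementwise) and `rotation` (payload: an orthogonal `d x d`
#' matrix with determinant +1, acting by matrix multiplication).
#'
#' @param kind One of `"index_permutation"`, `"sign_flip"`, `"rotation"`.
#' @param payload Permutation vector, sign vector, or rotation matrix.
#' @return An object of class `"transformation"`.
#' @examples
#' g <- transformation("index_permutation", c(2, 3, 1))
#' apply_transformation(g, c(10, 20, 30))
#' @export
transformation <- function(kind = c("index_permutation", "sign_flip", "rotation"),
                           payload) {
  kind <- match.arg(kind)
  if (kind == "index_permutation") {
    p <- as.integer(payload)
    n <- length(p)
    if (n < 1L || !identical(sort(p), seq_len(n)))
      stop("index_permutation payload must contain each of 1..n exactly once")
    payload <- p
  } else if (kind == "sign_flip") {
    s <- as.numeric(payload)
    if (length(s) < 1L || !all(s %in% c(-1, 1)))
      stop("sign_flip payload entries must be exactly -1 or +1")
    payload <- s
  } else {
    M <- as.matrix(payload)
    if (nrow(M) != ncol(M))
      stop("rotation payload must be a square matrix")
    d <- nrow(M)
    if (max(abs(crossprod(M) - diag(d))) > ROTATION_TOL)
      stop("rotation payload is not orthogonal within tolerance ", ROTATION_TOL)
    if (abs(det(M) - 1) > ROTATION_TOL)
      stop("rotation payload must have determinant +1")
    payload <- M
  }
  structure(list(kind = kind, payload = payload), class = "transformation")
}

#' @rdname transformation
#' @param p Permutation of `1:n`.
#' @export
perm_transform <- function(p) transformation("index_permutation", p)

#' @rdname transformation
#' @param s Vector with entries in `{-1, +1}`.
#' @export
sign_transform <- function(s) transformation("sign_flip", s)

#' @rdname transformation
#' @param M Orthogonal matrix with determinant +1.
#' @export
rotation_transform <- function(M) transformation("rotation", M)

#' Identity transformation of a given kind and dimension
#'
#' @param kind Transformation kind.
#' @param n Data dimension.
#' @return A `"transformation"` that maps every vector to itself.
#' @export
identity_transformation <- function(kind = c("index_permutation", "sign_flip",
                                             "rotation"), n) {
  kind <- match.arg(kind)
  switch(kind,
    index_permutation = perm_transform(seq_len(n)),
    sign_flip         = sign_transform(rep(1, n)),
    rotation          = rotation_transform(diag(n)))
}

#' @export
print.transformation <- function(x, ...) {
  cat("<transformation:", x$kind, "dim", transformation_dim(x), ">\n")
  invisible(x)
}

#' Dimension of the space a transformation acts on
#' @param g A transformation.
#' @return Integer dimension.
#' @export
transformation_dim <- function(g) {
  if (g$kind == "rotation") nrow(g$payload) else length(g$payload)
}

#' Test whether a transformation is the identity map
#' @param g A transformation.
#' @export
is_identity_transformation <- function(g) {
  switch(g$kind,
    index_permutation = all(g$payload == seq_along(g$payload)),
    sign_flip         = all(g$payload == 1),
    rotation          = max(abs(g$payload - diag(nrow(g$payload)))) <= ROTATION_TOL)
}

#' Apply a transformation to a data vector
#'
#' @param g A transformation.
#' @param x Numeric vector of matching dimension.
#' @return The transformed vector `g(x)`.
#' @export
apply_transformation <- function(g, x) {
  if (length(x) != transformation_dim(g))
    stop("data vector length ", length(x), " does not match transformation dimension ",
         transformation_dim(g))
  switch(g$kind,
    index_permutation = x[g$payload],
    sign_flip         = g$payload * x,
    rotation          = as.numeric(g$payload %*% x))
}

#' Compose two transformations
#'
#' Returns the map `x -> g(h(x))`.  For index permutations with the action
#' `(gx)[i] = x[p_g[i]]`, the composed payload is `q[i] = p_h[p_g[i]]`.
#'
#' @param g,h Transformations of the same kind and dimension.
#' @return The composition `g o h` as a transformation.
#' @export
compose <- function(g, h) {
  if (g$kind != h$kind)
    stop("cannot compose transformations of different kinds: ",
         g$kind, " and ", h$kind)
  if (transformation_dim(g) != transformation_dim(h))
    stop("cannot compose transformations of different dimensions")
  switch(g$kind,
    index_permutation = perm_transform(h$payload[g$payload]),
    sign_flip         = sign_transform(g$payload * h$payload),
    rotation          = rotation_transform(g$payload %*% h$payload))
}

#' Invert a transformation
#'
#' @param g A transformation.
#' @return The transformation `g^{-1}` with `compose(g, inverse(g))` the identity.
#' @export
inverse <- function(g) {
  switch(g$kind,
    index_permutation = {
      q <- integer(length(g$payload))
      q[g$payload] <- seq_along(g$payload)
      perm_transform(q)
    },
    sign_flip = g,                       # sign flips are involutions
    rotation  = rotation_transform(t(g$payload)))
}

# Canonical string encoding used for duplicate detection.  Exact for
# permutations and signs; rotations rounded to 12 decimals (they are
# constructed, not measured).
transformation_key <- function(g) {
  switch(g$kind,
    index_permutation = paste(g$payload, collapse = ","),
    sign_flip         = paste(as.integer(g$payload), collapse = ","),
    rotation          = paste(sprintf("%.12f", g$payload), collapse = ","))
}

#' Create an ordered set of transformations
#'
#' @param elements List of transformations, all of the same kind and dimension.
#' @param certificate One of `"unverified"`, `"verified_group"`,
#'   `"verified_not_group"`.  Use [verify_group()] to establish it.
#' @return An object of class `"transformation_set"`.
#' @export
transformation_set <- function(elements,
                               certificate = c("unverified", "verified_group",
                                               "verified_not_group")) {
  certificate <- match.arg(certificate)
  if (length(elements) == 0L) stop("a transformation set must be nonempty")
  stopifnot(all(vapply(elements, inherits, logical(1), "transformation")))
  kinds <- vapply(elements, function(g) g$kind, character(1))
  dims <- vapply(elements, transformation_dim, numeric(1))
  if (length(unique(kinds)) != 1L || length(unique(dims)) != 1L)
    stop("all elements must share one kind and one dimension")
  id_idx <- which(vapply(elements, is_identity_transformation, logical(1)))
  structure(list(elements = elements,
                 kind = kinds[[1L]],
                 dim = dims[[1L]],
                 group_certificate = certificate,
                 identity_index = if (length(id_idx)) id_idx[[1L]] else NA_integer_),
            class = "transformation_set")
}

#' @export
print.transformation_set <- function(x, ...) {
  cat("<transformation_set:", length(x$elements), x$kind,
      "elements, certificate:", x$group_certificate, ">\n")
  invisible(x)
}

#' Number of elements of a transformation set or group spec
#' @param G A `transformation_set` or `group_spec`.
#' @export
group_size <- function(G) {
  if (inherits(G, "transformation_set")) return(length(G$elements))
  if (inherits(G, "group_spec")) {
    return(switch(G$family,
      symmetric = factorial(G$n),
      sign_flip = 2^G$n))
  }
  stop("not a transformation set or group spec")
}

#' Verify the group axioms for a finite transformation set
#'
#' Checks that the set contains the identity, every element's inverse, and
#' every pairwise composition (closure), by exhaustive `O(#S^2)`
#' enumeration.  On failure the returned set carries the first violated
#' axiom and a witness in attributes `"violation"` and `"witness"`.
#'
#' @param S A `transformation_set`.
#' @param cap Refuse sets larger than this (the check is quadratic).
#' @return `S` with `group_certificate` set to `"verified_group"` or
#'   `"verified_not_group"`.
#' @examples
#' S <- transformation_set(lapply(list(c(1, 2), c(2, 1)), perm_transform))
#' verify_group(S)$group_certificate
#' @export
verify_group <- function(S, cap = 10000L) {
  stopifnot(inherits(S, "transformation_set"))
  N <- length(S$elements)
  if (N > cap)
    stop("set has ", N, " elements, above the verification cap (", cap,
         "); pass verified structure explicitly or raise the cap")
  keys <- vapply(S$elements, transformation_key, character(1))
  fail <- function(violation, witness) {
    S$group_certificate <- "verified_not_group"
    attr(S, "violation") <- violation
    attr(S, "witness") <- witness
    S
  }
  if (anyDuplicated(keys))
    return(fail("duplicate_elements", which(duplicated(keys))[1L]))
  if (is.na(S$identity_index))
    return(fail("missing_identity", NULL))
  key_env <- new.env(hash = TRUE, parent = emptyenv())
  for (k in keys) assign(k, TRUE, envir = key_env)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      comp <- compose(S$elements[[i]], S$elements[[j]])
      if (!exists(transformation_key(comp), envir = key_env))
        return(fail("closure_violation", c(i, j)))
    }
  }
  for (i in seq_len(N)) {
    if (!exists(transformation_key(inverse(S$elements[[i]])), envir = key_env))
      return(fail("missing_inverse", i))
  }
  S$group_certificate <- "verified_group"
  attr(S, "violation") <- NULL
  attr(S, "witness") <- NULL
  S
}

#' Orbit of a data vector under a transformation set
#'
#' Enumerates `{g(x) : g in S}` with duplicates removed.  Intended for
#' small sets (oracles and tests); the orbit is the conditioning event
#' behind every permutation test.
#'
#' @param x Numeric data vector.
#' @param S A `transformation_set`.
#' @return A list of distinct transformed vectors.
#' @export
orbit <- function(x, S) {
  stopifnot(inherits(S, "transformation_set"))
  vecs <- lapply(S$elements, apply_transformation, x = x)
  keys <- vapply(vecs, function(v) {
    v[v == 0] <- 0  # collapse -0 and +0
    paste(sprintf("%.15g", v), collapse = ",")
  }, character(1))
  vecs[!duplicated(keys)]
}

# ---- implicit group specs -------------------------------------------------

#' Implicitly represented large groups
#'
#' `sym_group(n)` is the symmetric group on `n` items (all `n!` index
#' permutations); `signflip_group(n)` is `{-1, +1}^n` acting elementwise.
#' Both are groups by construction, so they are accepted by the tests
#' without a quadratic verification pass, and both admit direct uniform
#' sampling (a uniform shuffle; iid fair signs) without enumeration.
#'
#' @param n Data dimension.
#' @return An object of class `"group_spec"`.
#' @export
sym_group <- function(n) {
  structure(list(family = "symmetric", kind = "index_permutation", n = as.integer(n)),
            class = "group_spec")
}

#' @rdname sym_group
#' @export
signflip_group <- function(n) {
  structure(list(family = "sign_flip", kind = "sign_flip", n = as.integer(n)),
            class = "group_spec")
}

#' @export
print.group_spec <- function(x, ...) {
  cat("<group_spec:", x$family, "n =", x$n, "(", format(group_size(x)),
      "elements ) >\n")
  invisible(x)
}

group_spec_identity <- function(G) {
  identity_transformation(G$kind, G$n)
}

draw_uniform_element <- function(G) {
  switch(G$family,
    symmetric = perm_transform(sample.int(G$n)),
    sign_flip = sign_transform(sample(c(-1, 1), G$n, replace = TRUE)))
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Materialize an implicit group as an explicit transformation set
#'
#' @param G A `group_spec`.
#' @param cap Refuse groups larger than this.
#' @return A `transformation_set` with certificate `"verified_group"`
#'   (groups by construction).
#' @export
materialize_group <- function(G, cap = 50000L) {
  stopifnot(inherits(G, "group_spec"))
  N <- group_size(G)
  if (N > cap)
    stop("group has ", format(N), " elements, above the materialization cap")
  elems <- switch(G$family,
    symmetric = lapply(all_permutations(G$n), perm_transform),
    sign_flip = {
      grid <- as.matrix(expand.grid(rep(list(c(1, -1)), G$n)))
      lapply(seq_len(nrow(grid)), function(i) sign_transform(grid[i, ]))
    })
  # put the identity first for convenience
  id_at <- which(vapply(elems, is_identity_transformation, logical(1)))[1L]
  elems <- c(elems[id_at], elems[-id_at])
  transformation_set(elems, certificate = "verified_group")
}

# ---- random draws (Definition-2 style vectors) ----------------------------

#' Draw a vector of random transformations with the identity adjoined
#'
#' Produces `(g_1, ..., g_w)` with `g_1` the identity and `g_2, ..., g_w`
#' uniform on the group `G`, drawn either with replacement (iid uniform on
#' `G`) or without replacement (a uniform sample from `G` minus the
#' identity; then `w <= #G`).  Prepending the identity is the
#' correctness-critical step that makes tests on the draws level-alpha.
#'
#' For implicitly represented large groups, with-replacement draws use
#' direct constructions and without-replacement draws use rejection
#' sampling with duplicate removal on a canonical encoding (the loop
#' errors out after `1000 * w` rejected proposals).
#'
#' @param G A `transformation_set` with certificate `"verified_group"`, or
#'   a `group_spec`.
#' @param w Total length of the returned vector, identity included.
#' @param scheme `"with_replacement"` or `"without_replacement"`.
#' @param seed Optional integer seed; every randomized operation in this
#'   package takes an explicit seed and leaves the caller's RNG state
#'   untouched when one is supplied.
#' @return An object of class `"drawn_transformations"` with fields
#'   `transformations`, `scheme`, `w`, `seed_record`.
#' @export
draw_transformations <- function(G, w,
                                 scheme = c("with_replacement",
                                            "without_replacement"),
                                 seed = NULL) {
  scheme <- match.arg(scheme)
  w <- as.integer(w)
  if (w < 1L) stop("w must be at least 1")
  N <- group_size(G)
  if (scheme == "without_replacement" && w > N)
    stop("w = ", w, " exceeds the group size ", format(N),
         " under without-replacement sampling")
  seed <- resolve_seed(seed)
  draws <- withr::with_seed(seed, {
    if (inherits(G, "transformation_set")) {
      if (G$group_certificate != "verified_group")
        stop("draw_transformations requires a verified group; run verify_group() first")
      id <- G$elements[[G$identity_index]]
      if (scheme == "with_replacement") {
        idx <- if (w > 1L) sample.int(N, w - 1L, replace = TRUE) else integer(0)
        c(list(id), G$elements[idx])
      } else {
        pool <- setdiff(seq_len(N), G$identity_index)
        idx <- if (w > 1L) sample(pool, w - 1L) else integer(0)
        c(list(id), G$elements[idx])
      }
    } else if (inherits(G, "group_spec")) {
      id <- group_spec_identity(G)
      if (scheme == "with_replacement") {
        c(list(id), replicate(w - 1L, draw_uniform_element(G), simplify = FALSE))
      } else {
        seen <- c(transformation_key(id))
        out <- vector("list", w - 1L)
        got <- 0L
        tries <- 0L
        while (got < w - 1L) {
          tries <- tries + 1L
          if (tries > 1000L * w)
            stop("without-replacement sampling exceeded ", 1000L * w,
                 " proposals; w is too close to #G for rejection sampling")
          cand <- draw_uniform_element(G)
          key <- transformation_key(cand)
          if (!(key %in% seen)) {
            got <- got + 1L
            out[[got]] <- cand
            seen <- c(seen, key)
          }
        }
        c(list(id), out)
      }
    } else stop("G must be a transformation_set or a group_spec")
  })
  structure(list(transformations = draws, scheme = scheme, w = w,
                 seed_record = list(seed = seed, kind = RNGkind()[1L])),
            class = "drawn_transformations")
}

#' @export
print.drawn_transformations <- function(x, ...) {
  cat("<drawn_transformations: w =", x$w, ", scheme =", x$scheme, ">\n")
  invisible(x)
}

# Resolve an optional seed: when absent, draw one from the current RNG so
# the operation is still recorded/replayable.
resolve_seed <- function(seed) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    stopifnot(!is.na(seed))
    return(seed)
  }
  sample.int(.Machine$integer.max, 1L)
}

# Deterministic derived seed for an independent substream (e.g. the
# auxiliary uniform of a randomized decision), so that enabling boundary
# randomization does not shift the transformation draws.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag)) * 2654435
  as.integer((as.double(seed) * 69069 + h) %% 2147483647)
}

# Serialize a transformation (kind + payload) for audit logs.
transformation_to_list <- function(g) {
  list(kind = g$kind,
       payload = if (g$kind == "rotation") as.numeric(g$payload) else g$payload,
       dim = transformation_dim(g))
}
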