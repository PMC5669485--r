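test_that("shuffled circular convolution is bilinear, non-commutative, norm-preserving", {
  d <- 1024L
  store <- new_label_store(d = d, seed = 1)
  set.seed(21)
  a <- stats::rnorm(d) / sqrt(d)
  b <- stats::rnorm(d) / sqrt(d)
  cc <- stats::rnorm(d) / sqrt(d)
  # non-commutative
  expect_gt(sqrt(sum((compose_vectors(a, b, store) -
                      compose_vectors(b, a, store))^2)), 0.1)
  # bilinear to machine precision
  expect_equal(compose_vectors(a, b + cc, store),
               compose_vectors(a, b, store) + compose_vectors(a, cc, store),
               tolerance = 1e-12)
  expect_equal(compose_vectors(a + b, cc, store),
               compose_vectors(a, cc, store) + compose_vectors(b, cc, store),
               tolerance = 1e-12)
  # approximately norm-preserving for random unit inputs
  norms <- replicate(100, {
    x <- stats::rnorm(d); x <- x / sqrt(sum(x^2))
    y <- stats::rnorm(d); y <- y / sqrt(sum(y^2))
    sqrt(sum(compose_vectors(x, y, store)^2))
  })
  expect_gt(mean(norms), 0.8)
  expect_lt(mean(norms), 1.2)
  expect_error(compose_vectors(a, stats::rnorm(10), store),
               "dimension mismatch")
})

test_that("label stores are deterministic, near-orthogonal, unit norm", {
  s1 <- new_label_store(d = 2048, seed = 42)
  s2 <- new_label_store(d = 2048, seed = 42)
  expect_identical(label_vector(s1, "syn", "NP"), label_vector(s2, "syn", "NP"))
  expect_false(identical(label_vector(s1, "syn", "NP"),
                         label_vector(s1, "word", "NP")))
  labs <- paste0("L", 1:20)
  V <- vapply(labs, function(l) label_vector(s1, "syn", l), numeric(2048))
  expect_equal(unname(sqrt(colSums(V^2))), rep(1, 20))
  G <- crossprod(V)
  off <- G[upper.tri(G)]
  expect_lt(mean(abs(off)), 0.05)
  # different master seed -> different vectors
  s3 <- new_label_store(d = 2048, seed = 7)
  expect_false(identical(label_vector(s1, "syn", "NP"),
                         label_vector(s3, "syn", "NP")))
})

test_that("fragment embeddings are deterministic and nearly orthogonal", {
  store <- new_label_store(d = 1024, seed = 42)
  f1 <- "(S NP (VP (VBZ w:binds) NP))"
  expect_identical(fragment_embedding(f1, store), fragment_embedding(f1, store))
  v1 <- fragment_embedding(f1, store)
  expect_equal(sum(v1 * v1) / sum(v1^2), 1)
  set.seed(3)
  coss <- replicate(100, {
    a <- fragment_embedding(
      sprintf("(S (NP (NN w:%s)) VP)", paste0("x", sample(1e6, 1))), store)
    b <- fragment_embedding(
      sprintf("(S NP (VP (VBZ w:%s)))", paste0("y", sample(1e6, 1))), store)
    abs(sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
  })
  expect_lt(mean(coss), 4 / sqrt(1024))
})

test_that("the DST recursion equals the brute-force fragment sum", {
  store <- new_label_store(d = 128, seed = 42)
  lambda <- 0.4
  set.seed(19)
  for (rep in 1:10) {
    lt <- lexicalize(rand_small_tree_string(max_nodes = 8))
    nv <- ppidstk:::dst_node_vectors(lt, store, lambda)
    frs <- enumerate_fragments(lt, max_count = 100000)
    for (j in seq_along(nv$ids)) {
      nid <- nv$ids[j]
      fsub <- Filter(function(f) f$root_id == nid, frs)
      brute <- Reduce(`+`, lapply(fsub, function(f)
        fragment_embedding(f$sig, store, lambda)))
      expect_lt(max(abs(brute - nv$S[, j])), 1e-10)
    }
  }
})

test_that("DST matrices: base case, zero embeddings, kernel positivity", {
  store <- new_label_store(d = 64, seed = 42)
  lambda <- 0.4
  E <- embedding_table(rbind(word = c(3, 0, 0)))
  lt <- lexicalize("(NN word)")
  Tm <- dst_matrix(lt, store, E, lambda)
  base <- sqrt(lambda) * compose_vectors(label_vector(store, "syn", "NN"),
                                         label_vector(store, "word", "word"),
                                         store)
  expect_equal(Tm$matrix, base %o% c(1, 0, 0), tolerance = 1e-12)
  expect_gte(dstk(Tm, Tm), 0)
  # all-OOV heads under the zero policy annihilate the matrix
  Ez <- embedding_table(rbind(other = c(1, 0)), oov = "zero")
  lt2 <- lexicalize("(S (NP (NN foo)) (VP (VBZ bar)))")
  T0 <- dst_matrix(lt2, store, Ez, lambda)
  expect_true(all(T0$matrix == 0))
  expect_equal(dstk(T0, T0), 0)
  T3 <- dst_matrix(lt2, store, embedding_table(rbind(a = c(1, 0, 0, 0))), lambda)
  expect_error(dstk(Tm, T3), "shape mismatch")
})

test_that("same master seed reproduces identical Gram matrices bitwise", {
  set.seed(30)
  trees <- replicate(5, template_tree_string())
  E <- uniform_embeddings(c("PROT", "kinase", "receptor", "complex",
                            "binds", "activates", "inhibits", "regulates",
                            "the", "with"))
  gram_of <- function(seed) {
    st <- new_label_store(d = 256, seed = seed)
    Ts <- lapply(trees, function(s) dst_matrix(lexicalize(s), st, E, 0.4))
    outer(seq_along(Ts), seq_along(Ts),
          Vectorize(function(i, j) dstk(Ts[[i]], Ts[[j]])))
  }
  expect_identical(gram_of(42), gram_of(42))
  expect_false(identical(gram_of(42), gram_of(43)))
})

test_that("the distributed kernel approximates the exact kernel, improving with d", {
  set.seed(11)
  gen <- generate_corpus(synth_config(n_sentences = 60, seed = 5))
  E <- build_embeddings(gen$corpus, k = 8)
  lambda <- 0.4
  pairs <- replicate(20, list(a = lexicalize(template_tree_string()),
                              b = lexicalize(template_tree_string())),
                     simplify = FALSE)
  exacts <- vapply(pairs, function(p) exact_stk(p$a, p$b, E, lambda), 0)
  err_at <- function(d) {
    st <- new_label_store(d = d, seed = 42)
    mean(vapply(seq_along(pairs), function(i) {
      Ta <- dst_matrix(pairs[[i]]$a, st, E, lambda)
      Tb <- dst_matrix(pairs[[i]]$b, st, E, lambda)
      abs(dstk(Ta, Tb) - exacts[i]) / (abs(exacts[i]) + 1e-9)
    }, 0))
  }
  e_small <- err_at(256)
  e_large <- err_at(2048)
  expect_lt(e_large, e_small)
  expect_lt(e_large, 0.25)
})
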