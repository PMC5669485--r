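test_that("co-occurrence counting is symmetric and per occurrence pair", {
  C <- count_cooccurrences(list(c("PROT1", "binds", "PROT2")))
  expect_equal(C$counts["PROT1", "binds"], 1)
  expect_equal(C$counts["binds", "PROT1"], 1)
  expect_equal(C$counts["PROT1", "PROT2"], 1)
  expect_equal(unname(diag(C$counts)), rep(0, 3))
  # repeated token: counted per ordered occurrence pair
  C2 <- count_cooccurrences(list(c("a", "a", "b")))
  expect_equal(C2$counts["a", "a"], 2)  # (1,2) and (2,1)
  expect_equal(C2$counts["a", "b"], 2)
  # sentence scope isolates sentences
  C3 <- count_cooccurrences(list(c("a", "b"), c("c", "d")))
  expect_equal(C3$counts["a", "c"], 0)
  expect_equal(C3$counts["a", "b"], 1)
  expect_error(count_cooccurrences(list()), "empty corpus")
  # window scope restricts the pair distance
  C4 <- count_cooccurrences(list(c("a", "b", "c", "d")), scope = "window",
                            window = 1L)
  expect_equal(C4$counts["a", "b"], 1)
  expect_equal(C4$counts["a", "c"], 0)
})

test_that("PPMI matches the closed form and clips at zero", {
  M <- matrix(c(10, 0, 0, 10), 2, 2,
              dimnames = list(c("w1", "w2"), c("c1", "c2")))
  P <- pmi_weight(M)
  expect_equal(P["w1", "c1"], log(2))
  expect_equal(P["w2", "c2"], log(2))
  expect_equal(P["w1", "c2"], 0)
  # independence (all cells equal) -> 0 everywhere
  expect_true(all(pmi_weight(matrix(3, 4, 4)) == 0))
  # non-negative on random count matrices
  set.seed(8)
  for (i in 1:10) {
    Mr <- matrix(rpois(30, 2), 5, 6)
    if (sum(Mr) == 0) next
    expect_true(all(pmi_weight(Mr) >= 0))
  }
})

test_that("SVD reduction is exact at full rank and Eckart-Young at lower rank", {
  set.seed(9)
  # rank-1 matrix, k = 1: perfect reconstruction of row inner products
  u <- stats::rnorm(6)
  v <- stats::rnorm(4)
  M <- u %o% v
  rownames(M) <- paste0("w", 1:6)
  E <- svd_reduce(M, 1)
  expect_equal(tcrossprod(E$vectors), tcrossprod(M), tolerance = 1e-10)
  # diagonal matrix: word vectors stay orthogonal
  D <- diag(c(3, 2, 1))
  rownames(D) <- c("a", "b", "c")
  Ed <- svd_reduce(D, 3)
  G <- tcrossprod(Ed$vectors)
  expect_equal(G, diag(c(9, 4, 1)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # Eckart-Young: rank-k residual equals the tail singular values
  for (i in 1:5) {
    Mr <- matrix(stats::rnorm(15 * 12), 15, 12)
    rownames(Mr) <- paste0("w", 1:15)
    k <- sample(2:6, 1)
    dec <- svd(Mr)
    Ek <- svd_reduce(Mr, k)
    # reconstruct with right singular vectors recovered from the
    # (sign-fixed) word vectors themselves: V_k = M' U_k / sigma_k
    Uk <- Ek$vectors %*% diag(1 / dec$d[seq_len(k)], k, k)
    Vk <- crossprod(Mr, Uk) %*% diag(1 / dec$d[seq_len(k)], k, k)
    recon <- Ek$vectors %*% t(Vk)
    expect_equal(sqrt(sum((Mr - recon)^2)),
                 sqrt(sum(dec$d[-seq_len(k)]^2)), tolerance = 1e-8)
  }
  expect_error(svd_reduce(M, 10), "exceeds")
  # deterministic across repeated calls (sign fixed)
  Mr <- matrix(stats::rnorm(64), 8, 8, dimnames = list(paste0("w", 1:8), NULL))
  expect_identical(svd_reduce(Mr, 3)$vectors, svd_reduce(Mr, 3)$vectors)
})

test_that("lookup honours OOV policies and the PROT alias", {
  V <- rbind(PROT = c(3, 4), binds = c(1, 0))
  E <- embedding_table(V, oov = "zero")
  expect_equal(embedding_lookup(E, "binds"), c(1, 0))
  expect_equal(sqrt(sum(embedding_lookup(E, "PROT")^2)), 1)  # unit norm
  expect_equal(embedding_lookup(E, "unknown"), c(0, 0))
  expect_equal(embedding_lookup(E, "PROT1"), embedding_lookup(E, "PROT"))
  expect_equal(embedding_lookup(E, "PROT2"), embedding_lookup(E, "PROT"))
  Eh <- embedding_table(V, oov = "hash")
  h1 <- embedding_lookup(Eh, "unknown")
  expect_identical(h1, embedding_lookup(Eh, "unknown"))
  expect_equal(sqrt(sum(h1^2)), 1)
  expect_false(identical(h1, embedding_lookup(Eh, "unknown2")))
})

test_that("the embedding pipeline is deterministic and files round-trip", {
  gen <- generate_corpus(synth_config(n_sentences = 25, seed = 4))
  E1 <- build_embeddings(gen$corpus, k = 6)
  E2 <- build_embeddings(gen$corpus, k = 6)
  expect_identical(E1$vectors, E2$vectors)
  expect_true("PROT" %in% rownames(E1$vectors))
  p <- tempfile()
  write_embeddings(E1, p)
  hdr <- strsplit(readLines(p, n = 1), " ")[[1]]
  expect_equal(as.integer(hdr), c(nrow(E1$vectors), E1$k))
  back <- read_embeddings(p)
  expect_equal(back$vectors, E1$vectors, tolerance = 1e-12)
})
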