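test_that("head percolation follows the rule table", {
  lt <- lexicalize("(S (NP (NN PROT1)) (VP (VBZ binds) (NP (NN PROT2))))")
  expect_equal(lt$root$head_word, "binds")   # S -> VP -> VBZ
  expect_equal(lt$root$head_pos, "VBZ")
  nd <- lex_nodes(lt)
  expect_equal(nd$head_word[nd$label == "NP" & nd$id < 4], "PROT1")

  single <- lexicalize("(NN PROT1)")
  expect_equal(single$root$head_word, "PROT1")

  # unknown category defaults to rightmost child
  lt2 <- lexicalize("(FOO (NN a) (NN b))")
  expect_equal(lt2$root$head_word, "b")
})

test_that("the keyword override re-heads the spine above the keyword", {
  s <- "(S (NP (NN PROT1) (CC and) (NN PROT2)) (VP (VBP interact)))"
  plain <- lexicalize(s)
  expect_equal(plain$root$head_word, "interact")  # S -> VP already
  # keyword inside the subject NP, nowhere near the Collins head
  s2 <- "(S (NP (NP (DT the) (NN interaction)) (PP (IN of) (NP (NN PROT1)))) (VP (VBD was) (VP (VBN observed))))"
  no_override <- lexicalize(s2)
  expect_equal(no_override$root$head_word, "was")
  with_override <- lexicalize(s2, keyword_index = 2L)
  expect_equal(with_override$root$head_word, "interaction")
  # nodes not dominating the keyword keep their percolated head
  nd <- lex_nodes(with_override)
  expect_equal(nd$head_word[nd$label == "VBD"], "was")
  expect_error(lexicalize(s2, keyword_index = 99L), "leaf range")
  expect_error(lexicalize(s, tokens = c("wrong", "tokens")),
               "do not match")
})

test_that("the toy tree has exactly the six expected fragments", {
  lt <- lexicalize("(A (B b) (C c))")
  fr <- enumerate_fragments(lt)
  expect_length(fr, 6)
  sigs <- vapply(fr, `[[`, character(1), "sig")
  expect_setequal(sigs, c("(A B C)", "(A (B w:b) C)", "(A B (C w:c))",
                          "(A (B w:b) (C w:c))", "(B w:b)", "(C w:c)"))
  expect_equal(count_fragments(lt)$total, 6)
  expect_length(enumerate_fragments(lexicalize("(NN x)")), 1)
  expect_error(enumerate_fragments(lt, max_count = 3), "exceeds")
})

test_that("enumeration matches the recursive count formula on random trees", {
  set.seed(41)
  for (i in 1:50) {
    lt <- lexicalize(rand_small_tree_string(max_nodes = 8))
    fr <- enumerate_fragments(lt, max_count = 100000)
    expect_equal(length(fr), count_fragments(lt)$total)
    # no duplicate (root, signature) combinations
    key <- paste(vapply(fr, `[[`, 0L, "root_id"),
                 vapply(fr, `[[`, "", "sig"))
    expect_false(anyDuplicated(key) > 0)
  }
})

test_that("exact smoothed kernel: symmetry, annihilation, zero-match", {
  set.seed(13)
  E <- embedding_table(matrix(stats::rnorm(5 * 4), 5, 4,
                              dimnames = list(c("prot", "binds", "the",
                                                "kinase", "with"), NULL)))
  for (i in 1:5) {
    ta <- lexicalize(rand_small_tree_string())
    tb <- lexicalize(rand_small_tree_string())
    expect_equal(exact_stk(ta, tb, E), exact_stk(tb, ta, E))
  }
  # orthogonal head vectors between the trees -> 0
  Eo <- embedding_table(rbind(a = c(1, 0), b = c(0, 1)))
  ta <- lexicalize("(X (P a))")
  tb <- lexicalize("(X (P b))")
  expect_equal(exact_stk(ta, tb, Eo), 0)
  # no structurally matching fragments -> 0
  tc <- lexicalize("(Y (Q a))")
  expect_equal(exact_stk(ta, tc, Eo), 0)
})

test_that("with identical unit heads the kernel equals the DP subset-tree kernel", {
  set.seed(77)
  vocab <- c("prot", "binds", "the", "kinase", "with")
  E <- uniform_embeddings(vocab)
  lambda <- 0.4
  for (i in 1:20) {
    sa <- rand_small_tree_string()
    sb <- if (i %% 4 == 0) sa else rand_small_tree_string()
    got <- exact_stk(lexicalize(sa), lexicalize(sb), E, lambda)
    want <- sst_kernel_dp(sa, sb, lambda)
    expect_equal(got, want, tolerance = 1e-10)
  }
})
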