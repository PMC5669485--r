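test_that("inclusive charOffsets convert to half-open spans and round-trip", {
  corpus <- read_ppi_xml(tiny_corpus_xml())
  expect_length(corpus, 1)
  s <- corpus[[1]]
  expect_equal(s$entities$start, c(4L, 20L))
  expect_equal(s$entities$end, c(8L, 24L))
  expect_equal(s$entities$surface, c("PRP9", "SNF1"))
  expect_equal(s$pairs$label, "positive")
  # token spans tile the covered text without overlap
  toks <- s$tokens
  expect_true(all(toks$start < toks$end))
  expect_true(all(diff(toks$start) > 0))
  expect_true(all(toks$end[-nrow(toks)] <= toks$start[-1]))
  expect_equal(substring(s$text, toks$start + 1, toks$end), toks$token)

  out <- tempfile(fileext = ".xml")
  write_ppi_xml(corpus, out)
  back <- read_ppi_xml(out)
  expect_equal(back[[1]]$entities, s$entities)
  expect_equal(back[[1]]$pairs$label, s$pairs$label)
  expect_equal(back[[1]]$text, s$text)
})

test_that("malformed corpora are rejected with informative errors", {
  p <- tempfile(fileext = ".xml")
  writeLines(c("<corpus><document id='d'>",
               "<sentence id='s' text='AA bb'>",
               "<entity id='e1' charOffset='0-1' text='AA'/>",
               "<pair id='p' e1='e1' e2='missing' interaction='True'/>",
               "</sentence></document></corpus>"), p)
  expect_error(read_ppi_xml(p), "unknown entity")

  writeLines(c("<corpus><document id='d'>",
               "<sentence id='s' text='AA bb'>",
               "<entity id='e1' charOffset='3-9' text='bb'/>",
               "</sentence></document></corpus>"), p)
  expect_error(read_ppi_xml(p), "outside sentence bounds")

  writeLines("<corpus><bad", p)
  expect_error(read_ppi_xml(p), "malformed XML")
})

test_that("bracketed tree files are validated and aligned", {
  p <- tempfile()
  writeLines(c("(S (NP (NN PROT1)) (VP (VBZ binds) (NP (NN PROT2))))",
               "(NN x)"), p)
  trees <- read_ptb_trees(p)
  expect_length(trees, 2)

  writeLines("(S (NP", p)
  expect_error(read_ptb_trees(p), "unbalanced")

  writeLines(c("#id=s1\t(NN a)", "#id=s2\t(NN b)"), p)
  trees <- read_ptb_trees(p)
  expect_named(trees, c("s1", "s2"))
  out <- tempfile()
  write_ptb_trees(trees, out)
  expect_identical(read_ptb_trees(out), trees)

  corpus <- read_ppi_xml(tiny_corpus_xml())
  expect_error(attach_parses(corpus, c("(NN a)", "(NN b)")),
               "count mismatch")
  good <- paste0("(S (NP (DT the) (NN PRP9) (NN gene)) ",
                 "(VP (VBZ binds) (NP (NN SNF1)) (ADVP (RB here))))")
  corpus <- attach_parses(corpus, good)
  expect_identical(corpus[[1]]$parse, good)
  expect_error(attach_parses(corpus, "(S (NN wrong))"),
               "do not match tokens")
})

test_that("instances blind the focus pair and distractors on tokens", {
  s <- table1_sentence()
  inst <- make_instances(s)
  expect_length(inst, 1)
  toks <- inst[[1]]$tokens
  expect_equal(sum(toks == "PROT1"), 1)
  expect_equal(sum(toks == "PROT2"), 1)
  expect_equal(sum(toks == "PROT"), 0)
  # multiword entity collapses to one token
  expect_equal(length(toks), nrow(s$tokens) - 1)
  # non-entity tokens unchanged
  expect_true(all(c("indicate", "that", "the", "and", "interact", ".")
                  %in% toks))
})

test_that("pair enumeration, distractor counts and self-pairs behave", {
  text <- "AA meets BB and CC today"
  ents <- data.frame(id = c("e1", "e2", "e3"),
                     start = c(0L, 9L, 16L), end = c(2L, 11L, 18L),
                     surface = c("AA", "BB", "CC"),
                     stringsAsFactors = FALSE)
  pairs <- data.frame(e1 = c("e1", "e1", "e2"), e2 = c("e2", "e3", "e3"),
                      label = c("positive", "negative", "negative"),
                      stringsAsFactors = FALSE)
  s <- ppidstk:::new_ppi_sentence("x1", text, ents, pairs)
  inst <- make_instances(s)
  expect_length(inst, 3)
  for (i in inst) {
    expect_equal(sum(i$tokens == "PROT1"), 1)
    expect_equal(sum(i$tokens == "PROT2"), 1)
    expect_equal(sum(i$tokens == "PROT"), 1)  # 3 entities - focus pair
  }
  # PROT1 is the leftmost mention regardless of pair order
  swapped <- s
  swapped$pairs <- data.frame(e1 = "e3", e2 = "e1", label = "negative",
                              stringsAsFactors = FALSE)
  i2 <- make_instances(swapped)[[1]]
  expect_lt(i2$pos1, i2$pos2)
  expect_equal(i2$e1, "e1")

  selfp <- s
  selfp$pairs <- data.frame(e1 = "e1", e2 = "e1", label = "positive",
                            stringsAsFactors = FALSE)
  expect_warning(out <- make_instances(selfp), "self-pair")
  expect_length(out, 0)
})

test_that("blinding property holds across a generated corpus", {
  gen <- generate_corpus(synth_config(n_sentences = 40, seed = 5,
                                      distractor_prob = 0.5))
  for (s in gen$corpus) {
    for (i in make_instances(s)) {
      expect_equal(sum(i$tokens == "PROT1"), 1)
      expect_equal(sum(i$tokens == "PROT2"), 1)
      expect_equal(sum(i$tokens == "PROT"), nrow(s$entities) - 2L)
      # blinded parse stays aligned with the blinded token sequence
      expect_identical(ptb_leaves(ptb_parse(i$parse)), i$tokens)
    }
  }
})
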