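# Shared fixtures: all built in code at test time.

# The worked feature-extraction example sentence with its two protein
# mentions (the second one multiword).
table1_sentence <- function() {
  text <- paste0("Biochemical complementation experiments also indicate ",
                 "that the PRP9 and PRP11 proteins interact.")
  s1 <- regexpr("PRP9", text)[1] - 1L
  s2 <- regexpr("PRP11 proteins", text)[1] - 1L
  entities <- data.frame(
    id = c("e1", "e2"),
    start = c(s1, s2),
    end = c(s1 + nchar("PRP9"), s2 + nchar("PRP11 proteins")),
    surface = c("PRP9", "PRP11 proteins"),
    stringsAsFactors = FALSE
  )
  pairs <- data.frame(e1 = "e1", e2 = "e2", label = "positive",
                      stringsAsFactors = FALSE)
  ppidstk:::new_ppi_sentence("t1.s1", text, entities, pairs)
}

# Minimal unified-XML corpus written to a temp file; returns the path.
tiny_corpus_xml <- function(path = tempfile(fileext = ".xml")) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<corpus source="fixture">',
    ' <document id="d1">',
    '  <sentence id="d1.s1" text="the PRP9 gene binds SNF1 here">',
    '   <entity id="d1.s1.e1" charOffset="4-7" text="PRP9" type="protein"/>',
    '   <entity id="d1.s1.e2" charOffset="20-23" text="SNF1" type="protein"/>',
    '   <pair id="d1.s1.p1" e1="d1.s1.e1" e2="d1.s1.e2" interaction="True"/>',
    '  </sentence>',
    ' </document>',
    '</corpus>'
  ), path)
  path
}

# Random small lexicalized trees for property tests: preterminals carry
# words from a tiny shared vocabulary so random pairs still share
# fragments.
rand_small_tree_string <- function(max_nodes = 8,
                                   vocab = c("prot", "binds", "the",
                                             "kinase", "with")) {
  env <- new.env(parent = emptyenv())
  env$left <- max_nodes
  gen <- function(depth) {
    if (env$left <= 1 || depth > 3 || stats::runif(1) < 0.35) {
      env$left <- env$left - 1
      pos <- sample(c("NN", "VBZ", "IN", "DT"), 1)
      return(paste0("(", pos, " ", sample(vocab, 1), ")"))
    }
    env$left <- env$left - 1
    k <- sample(1:2, 1)
    kids <- vapply(seq_len(k), function(i) gen(depth + 1), character(1))
    paste0("(", sample(c("S", "NP", "VP", "PP"), 1), " ",
           paste(kids, collapse = " "), ")")
  }
  gen(0)
}

# Clause-template trees over a shared small vocabulary: random pairs have
# substantial fragment overlap, so the exact smoothed kernel is bounded
# away from zero (the regime where relative error is meaningful).
template_tree_string <- function() {
  verbs <- c("binds", "activates", "inhibits", "regulates")
  nouns <- c("PROT", "results", "interaction", "binding")
  v <- sample(verbs, 1)
  n1 <- sample(nouns, 1)
  n2 <- sample(nouns, 1)
  switch(sample(3, 1),
    sprintf("(S (NP (NN %s)) (VP (VBZ %s) (NP (NN %s))))", n1, v, n2),
    sprintf("(S (NP (NN %s)) (VP (VBZ %s) (PP (IN with) (NP (NN %s)))))",
            n1, v, n2),
    sprintf("(S (NP (DT the) (NN %s)) (VP (VBZ %s) (NP (NN %s))))",
            n1, v, n2)
  )
}

# Embedding table with all-identical unit vectors: the smoothed kernel
# then reduces to the purely structural subset-tree kernel.
uniform_embeddings <- function(words, k = 4) {
  v <- matrix(rep(1 / sqrt(k), k), nrow = length(words), ncol = k,
              byrow = TRUE, dimnames = list(words, NULL))
  embedding_table(v)
}

# Independent dynamic-programming subset-tree kernel (Collins-Duffy
# recursion), used as the structural oracle: for equal unit head vectors
# exact_stk must coincide with it. Operates directly on ptb_parse()
# output, no shared code with the enumeration path.
sst_kernel_dp <- function(sa, sb, lambda) {
  ta <- ppidstk::ptb_parse(sa)
  tb <- ppidstk::ptb_parse(sb)
  nodes <- function(t) {
    out <- list()
    walk <- function(n) {
      out[[length(out) + 1]] <<- n
      if (is.null(n$word)) lapply(n$children, walk)
      invisible(NULL)
    }
    walk(t)
    out
  }
  delta <- function(n1, n2) {
    if (n1$label != n2$label) return(0)
    if (!is.null(n1$word) || !is.null(n2$word)) {
      if (is.null(n1$word) || is.null(n2$word)) return(0)
      return(if (n1$word == n2$word) lambda else 0)
    }
    if (length(n1$children) != length(n2$children)) return(0)
    labs1 <- vapply(n1$children, `[[`, character(1), "label")
    labs2 <- vapply(n2$children, `[[`, character(1), "label")
    if (!identical(labs1, labs2)) return(0)
    lambda * prod(vapply(seq_along(n1$children), function(i) {
      1 + delta(n1$children[[i]], n2$children[[i]])
    }, numeric(1)))
  }
  total <- 0
  for (n1 in nodes(ta)) for (n2 in nodes(tb)) total <- total + delta(n1, n2)
  total
}

# Shared prepared corpus for the Gram/CV tests (built once per run).
.shared <- new.env(parent = emptyenv())
shared_prep <- function() {
  if (is.null(.shared$prep)) {
    cfg <- kernel_config(d = 256, k = 8, seed = 42)
    gen <- generate_corpus(synth_config(n_sentences = 100, seed = 99))
    .shared$gen <- gen
    .shared$cfg <- cfg
    .shared$prep <- prepare_instances(gen$corpus, cfg)
  }
  .shared
}
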