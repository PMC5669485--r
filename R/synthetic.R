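# Deterministic synthetic PPI corpus generator. Each template is built as
# a constituency tree; the sentence tokens are its leaves, so every
# sentence ships with a gold bracketed parse by construction. Positive
# templates realize an interaction verb (or nominalization) relating the
# two proteins; negative templates co-mention proteins without relating
# them, some with a non-relational interaction keyword as a distractor.
# Gene symbols come from a letters+digits grammar so the NUM rule of the
# normalizer is exercised but must not fire on them.

nn_ <- function(label, word) list(label = label, word = word)
nt_ <- function(label, ...) list(label = label, children = list(...))

# Interaction verbs are drawn Zipf-like (probability proportional to
# 1/rank), giving the long-tailed lexical distribution of real abstracts:
# a sparse lexical learner sees many test-time verbs only rarely in
# training, while the structural kernel matches the shared clause spine
# regardless of the verb's identity.
SYNTH_VERBS <- c("binds", "activates", "inhibits", "phosphorylates",
                 "regulates", "stimulates", "represses", "modulates",
                 "recruits", "cleaves", "stabilizes", "sequesters",
                 "acetylates", "methylates", "ubiquitinates", "degrades",
                 "tethers", "anchors", "antagonizes", "attenuates",
                 "transactivates", "destabilizes", "suppresses",
                 "triggers", "targets", "docks", "couples", "links",
                 "contacts", "upregulates")
SYNTH_WITH_VERBS <- c("interacts", "associates", "cooperates", "dimerizes",
                      "colocalizes", "synergizes", "heterodimerizes",
                      "coimmunoprecipitates", "copurifies", "cosediments",
                      "cofractionates", "coelutes", "coassembles",
                      "cocrystallizes")
SYNTH_PASSIVES <- c("phosphorylated", "activated", "inhibited", "regulated",
                    "stimulated", "repressed", "recruited", "stabilized",
                    "acetylated", "ubiquitinated", "sequestered",
                    "degraded", "methylated", "antagonized")
SYNTH_ADVERBS <- c("directly", "strongly", "specifically", "efficiently",
                   "selectively", "weakly", "rapidly", "transiently",
                   "constitutively", "markedly")
SYNTH_OPENERS <- c("moreover", "furthermore", "interestingly", "notably",
                   "previously", "importantly", "additionally",
                   "consistently", "surprisingly", "finally")
SYNTH_TAILS <- list(
  c("in", "vivo"), c("in", "vitro"), c("in", "yeast"), c("in", "neurons"),
  c("in", "fibroblasts"), c("in", "lymphocytes"), c("in", "mitochondria"),
  c("in", "oocytes")
)

# Plural (VBP) forms for coordinated subjects: "A and B interact".
SYNTH_COORD_VERBS <- c("interact", "associate", "cooperate", "dimerize",
                       "colocalize", "synergize", "heterodimerize",
                       "coimmunoprecipitate", "oligomerize", "crosslink",
                       "copurify", "cosediment", "cofractionate", "coelute",
                       "coassemble", "coaggregate")
# Passive interaction participles for "A and B were crosslinked":
# structurally identical to the co-mention negatives below, so only the
# participle's identity (and its distributional vector) carries the label.
SYNTH_COORD_PASSIVES <- c("crosslinked", "coimmunoprecipitated",
                          "colocalized", "heterodimerized", "tethered",
                          "coupled", "copurified", "cosedimented",
                          "cofractionated", "coassembled", "coeluted",
                          "cocrystallized")
# Non-interaction participles for co-mention negatives.
SYNTH_NEG_PARTICIPLES <- c("purified", "expressed", "isolated", "detected",
                           "sequenced", "analysed", "identified", "cloned",
                           "characterized", "quantified", "measured",
                           "visualized")
SYNTH_REPORT_VERBS <- c("indicate", "suggest", "show", "demonstrate",
                        "confirm", "reveal")
# Interaction nouns: nominalization heads and assay-tail vocabulary.
SYNTH_ASSAY_NOUNS <- c("interaction", "binding", "association")
# Processes a coordinated pair can be "required for" (keyword-bearing
# negatives).
SYNTH_PROCESS_NOUNS <- c("binding", "dimerization", "activity", "stability",
                         "degradation", "localization")
# Non-protein grammatical objects for the two-clause negatives.
SYNTH_NONPROT_OBJECTS <- c("DNA", "RNA", "chromatin", "actin", "tubulin",
                           "calmodulin")
# Experimental-method nouns for the "detected by <method> with B"
# negatives; these sentences reuse the by/with function words of the
# passive and with-PP positives.
SYNTH_METHOD_NOUNS <- c("immunoblotting", "immunostaining", "microscopy",
                        "spectrometry", "chromatography", "electrophoresis")

zipf_sample <- function(pool) {
  sample(pool, 1, prob = 1 / seq_along(pool))
}

#' Synthetic corpus configuration
#'
#' @param n_sentences Number of sentences (default 250).
#' @param pos_fraction Probability a sentence realizes an interaction
#'   template (default 0.4, mimicking the negative-skewed benchmark
#'   corpora).
#' @param label_noise Probability each pair label is flipped in the
#'   emitted corpus (truth table keeps the clean label).
#' @param distractor_prob Probability a positive sentence carries a third,
#'   non-interacting protein (exercises PROT blinding and protcount).
#' @param multiword_prob Probability the second protein name is a two-token
#'   mention (`<gene> protein`).
#' @param template_set Template family id (only `"default"`).
#' @param seed Master seed.
#' @return A `synth_config`.
#' @export
synth_config <- function(n_sentences = 250L, pos_fraction = 0.4,
                         label_noise = 0, distractor_prob = 0.05,
                         multiword_prob = 0.15, template_set = "default",
                         seed = 1L) {
  stopifnot(n_sentences >= 1, pos_fraction >= 0, pos_fraction <= 1,
            label_noise >= 0, label_noise <= 1,
            template_set == "default")
  structure(list(n_sentences = as.integer(n_sentences),
                 pos_fraction = pos_fraction, label_noise = label_noise,
                 distractor_prob = distractor_prob,
                 multiword_prob = multiword_prob,
                 template_set = template_set, seed = as.integer(seed)),
            class = "synth_config")
}

gene_symbol <- function() {
  paste0(paste(sample(LETTERS, sample(2:4, 1), replace = TRUE),
               collapse = ""),
         sample(0:99, 1))
}

distinct_genes <- function(n) {
  g <- character(0)
  while (length(g) < n) g <- unique(c(g, gene_symbol()))
  g[seq_len(n)]
}

gene_np <- function(gene, multiword = FALSE) {
  if (multiword) {
    list(node = nt_("NP", nn_("NN", gene), nn_("NN", "protein")),
         n_tokens = 2L, surface = paste(gene, "protein"))
  } else {
    list(node = nt_("NP", nn_("NN", gene)), n_tokens = 1L, surface = gene)
  }
}

# Each template returns list(tree, entities = list(surface strings in
# leaf order), pairs = data.frame(a, b, gold) over entity indices).
# Templates produce a core clause; finish() then applies class-neutral
# modifiers -- sentence openers, report frames ("these results show
# that ..."), locative tails -- to positives and negatives alike, so no
# peripheral context word gives the label away. Positives may instead
# draw an interaction-assay tail, which makes interaction verbs
# co-occur with interaction nouns and lets the distributional vectors
# of rare verbs cluster with the frequent ones.
synth_templates <- function(cfg) {
  tail_pp <- function(positive) {
    if (positive && stats::runif(1) < 0.5) {
      return(nt_("PP", nn_("IN", "in"),
                 nt_("NP", nn_("DT", sample(c("this", "a"), 1)),
                     nn_("NN", sample(SYNTH_ASSAY_NOUNS, 1)),
                     nn_("NN", sample(c("assay", "experiment"), 1)))))
    }
    tl <- SYNTH_TAILS[[sample(length(SYNTH_TAILS), 1)]]
    nt_("PP", nn_("IN", tl[1]), nt_("NP", nn_("NN", tl[2])))
  }
  finish <- function(kids, entities, pairs) {
    positive <- any(pairs$gold == "positive")
    core <- do.call(nt_, c(list("S"), kids))
    if (stats::runif(1) < 0.35) {
      core$children <- c(core$children, list(tail_pp(positive)))
    }
    tree <- if (stats::runif(1) < 0.25) {
      nt_("S", nt_("NP", nn_("DT", "these"), nn_("NNS", "results")),
          nt_("VP", nn_("VBP", sample(SYNTH_REPORT_VERBS, 1)),
              nt_("SBAR", nn_("IN", "that"), core)))
    } else {
      core
    }
    if (stats::runif(1) < 0.35) {
      tree$children <- c(list(nt_("ADVP",
                                  nn_("RB", sample(SYNTH_OPENERS, 1))),
                              nn_(",", ",")),
                         tree$children)
    }
    tree$children <- c(tree$children, list(nn_(".", ".")))
    list(tree = tree, entities = entities, pairs = pairs)
  }
  pair_df <- function(a, b, gold) data.frame(a = a, b = b, gold = gold,
                                             stringsAsFactors = FALSE)
  # transitive VP with an optional adverb between verb and object
  trans_vp <- function(obj_node) {
    kids <- list(nn_("VBZ", zipf_sample(SYNTH_VERBS)))
    if (stats::runif(1) < 0.35) {
      kids <- c(kids, list(nt_("ADVP", nn_("RB", sample(SYNTH_ADVERBS, 1)))))
    }
    do.call(nt_, c(list("VP"), kids, list(obj_node)))
  }
  coord_np <- function(g1, g2) {
    nt_("NP", nn_("NN", g1), nn_("CC", "and"), nn_("NN", g2))
  }
  aux_vbd <- function() nn_("VBD", sample(c("was", "is"), 1))
  list(
    p_trans = function() {
      g <- distinct_genes(2)
      e2 <- gene_np(g[2], stats::runif(1) < cfg$multiword_prob)
      finish(list(nt_("NP", nn_("NN", g[1])),
                  trans_vp(e2$node)),
             list(g[1], e2$surface), pair_df(1, 2, "positive"))
    },
    p_with = function() {
      g <- distinct_genes(2)
      finish(list(nt_("NP", nn_("NN", g[1])),
                  nt_("VP", nn_("VBZ", zipf_sample(SYNTH_WITH_VERBS)),
                      nt_("PP", nn_("IN", "with"),
                          nt_("NP", nn_("NN", g[2]))))),
             as.list(g), pair_df(1, 2, "positive"))
    },
    p_passive = function() {
      g <- distinct_genes(2)
      finish(list(nt_("NP", nn_("NN", g[1])),
                  nt_("VP", aux_vbd(),
                      nt_("VP", nn_("VBN", zipf_sample(SYNTH_PASSIVES)),
                          nt_("PP", nn_("IN", "by"),
                              nt_("NP", nn_("NN", g[2])))))),
             as.list(g), pair_df(1, 2, "positive"))
    },
    p_nom = function() {
      g <- distinct_genes(2)
      finish(list(nt_("NP",
                      nt_("NP", nn_("DT", "the"),
                          nn_("NN", sample(SYNTH_ASSAY_NOUNS, 1))),
                      nt_("PP", nn_("IN", "of"),
                          nt_("NP", nn_("NN", g[1]))),
                      nt_("PP", nn_("IN", "with"),
                          nt_("NP", nn_("NN", g[2])))),
                  nt_("VP", nn_("VBD", "was"),
                      nt_("VP", nn_("VBN", sample(c("observed", "detected",
                                                    "confirmed"), 1))))),
             as.list(g), pair_df(1, 2, "positive"))
    },
    p_coord = function() {
      g <- distinct_genes(2)
      vp_kids <- list(nn_("VBP", zipf_sample(SYNTH_COORD_VERBS)))
      if (stats::runif(1) < 0.35) {
        vp_kids <- c(vp_kids,
                     list(nt_("ADVP", nn_("RB", sample(SYNTH_ADVERBS, 1)))))
      }
      finish(list(coord_np(g[1], g[2]),
                  do.call(nt_, c(list("VP"), vp_kids))),
             as.list(g), pair_df(1, 2, "positive"))
    },
    p_coord_pass = function() {
      g <- distinct_genes(2)
      finish(list(coord_np(g[1], g[2]),
                  nt_("VP", nn_("VBD", "were"),
                      nt_("VP", nn_("VBN",
                                    zipf_sample(SYNTH_COORD_PASSIVES))))),
             as.list(g), pair_df(1, 2, "positive"))
    },
    p_distractor = function() {
      g <- distinct_genes(3)
      finish(list(nt_("PP", nn_("IN", "in"),
                      nt_("NP", nt_("NP", nn_("NNS", "cells")),
                          nt_("VP", nn_("VBG", "expressing"),
                              nt_("NP", nn_("NN", g[3]))))),
                  nn_(",", ","),
                  nt_("NP", nn_("NN", g[1])),
                  trans_vp(nt_("NP", nn_("NN", g[2])))),
             as.list(g),
             rbind(pair_df(1, 2, "positive"), pair_df(1, 3, "negative"),
                   pair_df(2, 3, "negative")))
    },
    n_coord = function() {
      g <- distinct_genes(2)
      # the source PP is optional: without it this clause is structurally
      # identical to the passive coordination positives, and only the
      # participle tells the classes apart
      inner <- list(nn_("VBN", zipf_sample(SYNTH_NEG_PARTICIPLES)))
      if (stats::runif(1) < 0.5) {
        inner <- c(inner,
                   list(nt_("PP", nn_("IN", "from"),
                            nt_("NP",
                                nn_("NN", sample(c("cell", "nuclear",
                                                   "tissue"), 1)),
                                nn_("NNS", "extracts")))))
      }
      finish(list(coord_np(g[1], g[2]),
                  nt_("VP", nn_("VBD", "were"),
                      do.call(nt_, c(list("VP"), inner)))),
             as.list(g), pair_df(1, 2, "negative"))
    },
    n_req = function() {
      g <- distinct_genes(2)
      finish(list(coord_np(g[1], g[2]),
                  nt_("VP", nn_("VBD", "were"),
                      nt_("VP", nn_("VBN", sample(c("required", "needed"),
                                                  1)),
                          nt_("PP", nn_("IN", "for"),
                              nt_("NP",
                                  nn_("NN", sample(SYNTH_PROCESS_NOUNS,
                                                   1))))))),
             as.list(g), pair_df(1, 2, "negative"))
    },
    n_detect = function() {
      g <- distinct_genes(2)
      finish(list(nt_("NP", nn_("NN", g[1])),
                  nt_("VP", aux_vbd(),
                      nt_("VP", nn_("VBN",
                                    sample(SYNTH_NEG_PARTICIPLES, 1)),
                          nt_("PP", nn_("IN", "in"),
                              nt_("NP",
                                  nt_("NP", nn_("DT", "the"),
                                      nn_("NN", sample(c("presence",
                                                         "absence"), 1))),
                                  nt_("PP", nn_("IN", "of"),
                                      nt_("NP", nn_("NN", g[2])))))))),
             as.list(g), pair_df(1, 2, "negative"))
    },
    n_method = function() {
      g <- distinct_genes(2)
      finish(list(nt_("NP", nn_("NN", g[1])),
                  nt_("VP", aux_vbd(),
                      nt_("VP", nn_("VBN",
                                    sample(SYNTH_NEG_PARTICIPLES, 1)),
                          nt_("PP", nn_("IN", "by"),
                              nt_("NP", nn_("NN",
                                            sample(SYNTH_METHOD_NOUNS, 1)))),
                          nt_("PP", nn_("IN", "with"),
                              nt_("NP", nn_("NN", g[2])))))),
             as.list(g), pair_df(1, 2, "negative"))
    },
    n_clause = function() {
      g <- distinct_genes(2)
      finish(list(nt_("S", nt_("NP", nn_("NN", g[1])),
                      trans_vp(nt_("NP",
                                   nn_("NN", sample(SYNTH_NONPROT_OBJECTS,
                                                    1))))),
                  nn_("IN", sample(c("whereas", "while"), 1)),
                  nt_("S", nt_("NP", nn_("NN", g[2])),
                      nt_("VP", nn_("VBD", "was"),
                          nt_("VP", nn_("VBN",
                                        sample(SYNTH_NEG_PARTICIPLES,
                                               1)))))),
             as.list(g), pair_df(1, 2, "negative"))
    },
    n_list = function() {
      g <- distinct_genes(2)
      finish(list(nt_("NP",
                      nt_("NP", nn_("NNS", sample(c("samples", "lysates",
                                                    "fractions",
                                                    "cultures"), 1))),
                      nt_("VP", nn_("VBG", sample(c("containing", "lacking",
                                                    "expressing"), 1)),
                          nt_("NP", nn_("NN", g[1]), nn_("CC", "or"),
                              nn_("NN", g[2])))),
                  nt_("VP", nn_("VBD", "were"),
                      nt_("VP", nn_("VBN", sample(c("analysed", "compared",
                                                    "examined"), 1))))),
             as.list(g), pair_df(1, 2, "negative"))
    }
  )
}

#' Generate a labelled synthetic PPI corpus
#'
#' Deterministic under `config$seed`. Returns the corpus (with parses
#' attached) and the gold truth table; optionally writes the unified XML,
#' the bracketed parse file (with `#id=` prefixes) and the truth CSV into
#' `dir`. Emitted labels are the gold labels flipped independently with
#' probability `label_noise`.
#'
#' @param config A `synth_config`.
#' @param dir Optional output directory.
#' @return List with `corpus` (a `ppi_corpus`), `truth` (data frame
#'   `sentence_id,e1,e2,gold,label,template`) and, when `dir` is given,
#'   `paths`.
#' @export
generate_corpus <- function(config = synth_config(), dir = NULL) {
  templates <- synth_templates(config)
  pos_names <- c("p_trans", "p_with", "p_passive", "p_nom", "p_coord",
                 "p_coord_pass")
  # Coordination-style positives ("A and B copurify / were crosslinked")
  # are drawn a little more often than clause positives: co-mention-style
  # interaction evidence is common in abstracts and is the hard case for
  # purely lexical features.
  pos_weights <- c(0.18, 0.18, 0.14, 0.14, 0.16, 0.20)
  neg_names <- c("n_coord", "n_detect", "n_clause", "n_list", "n_req",
                 "n_method")
  sentences <- list()
  truth <- NULL
  with_seed(derive_seed(config$seed, "synthetic-corpus"), {
    for (i in seq_len(config$n_sentences)) {
      pos <- stats::runif(1) < config$pos_fraction
      tname <- if (pos && stats::runif(1) < config$distractor_prob) {
        "p_distractor"
      } else if (pos) {
        sample(pos_names, 1, prob = pos_weights)
      } else {
        sample(neg_names, 1)
      }
      tpl <- templates[[tname]]()
      sid <- paste0("s", i)
      leaves <- ptb_leaves(tpl$tree)
      text <- paste(leaves, collapse = " ")
      # Character spans of the space-joined leaves.
      ends <- cumsum(nchar(leaves) + 1L) - 1L
      starts <- ends - nchar(leaves)
      ent_rows <- NULL
      for (j in seq_along(tpl$entities)) {
        surf <- tpl$entities[[j]]
        ewords <- strsplit(surf, " ", fixed = TRUE)[[1]]
        first <- find_entity_leaf(leaves, ewords, ent_rows)
        ent_rows <- rbind(ent_rows, data.frame(
          id = paste0(sid, ".e", j),
          start = starts[first],
          end = ends[first + length(ewords) - 1L],
          surface = surf, stringsAsFactors = FALSE
        ))
      }
      gold <- tpl$pairs$gold
      flip <- stats::runif(nrow(tpl$pairs)) < config$label_noise
      lab <- ifelse(flip, ifelse(gold == "positive", "negative", "positive"),
                    gold)
      pairs <- data.frame(e1 = ent_rows$id[tpl$pairs$a],
                          e2 = ent_rows$id[tpl$pairs$b],
                          label = lab, stringsAsFactors = FALSE)
      s <- new_ppi_sentence(sid, text, ent_rows, pairs)
      s$parse <- ptb_format(tpl$tree)
      sentences[[i]] <- s
      truth <- rbind(truth, data.frame(
        sentence_id = sid, e1 = pairs$e1, e2 = pairs$e2, gold = gold,
        label = lab, template = tname, stringsAsFactors = FALSE
      ))
    }
  })
  corpus <- structure(sentences, class = "ppi_corpus", source = "synthetic")
  out <- list(corpus = corpus, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    xml <- file.path(dir, "corpus.xml")
    trees <- file.path(dir, "trees.txt")
    tcsv <- file.path(dir, "truth.csv")
    write_ppi_xml(corpus, xml)
    tr <- vapply(corpus, `[[`, character(1), "parse")
    names(tr) <- vapply(corpus, `[[`, character(1), "id")
    write_ptb_trees(tr, trees)
    utils::write.csv(truth, tcsv, row.names = FALSE)
    out$paths <- c(corpus = xml, trees = trees, truth = tcsv)
  }
  out
}

# Locate the leaf index where an entity's word sequence starts, skipping
# starts already claimed by earlier entities.
find_entity_leaf <- function(leaves, ewords, ent_rows) {
  n <- length(ewords)
  for (i in seq_len(length(leaves) - n + 1L)) {
    if (all(leaves[i:(i + n - 1L)] == ewords)) {
      return(i)
    }
  }
  stop("internal generator error: entity words not found in leaves")
}

#' Validate a corpus against the format invariants
#'
#' Report-only checker: entity spans inside bounds and matching their
#' surface; pair endpoints resolving and no duplicate unordered pairs;
#' parse (when present) balanced with leaves equal to the token sequence.
#'
#' @param corpus A `ppi_corpus`.
#' @return Data frame `sentence_id,check,message` of violations (zero
#'   rows when clean).
#' @export
validate_corpus <- function(corpus) {
  bad <- list()
  flag <- function(sid, check, msg) {
    bad[[length(bad) + 1]] <<- data.frame(sentence_id = sid, check = check,
                                          message = msg,
                                          stringsAsFactors = FALSE)
  }
  for (s in corpus) {
    ent <- s$entities
    for (i in seq_len(nrow(ent))) {
      if (ent$start[i] < 0 || ent$end[i] > nchar(s$text) ||
          ent$start[i] >= ent$end[i]) {
        flag(s$id, "entity_span", paste0(ent$id[i], " out of bounds"))
      } else if (substring(s$text, ent$start[i] + 1, ent$end[i]) !=
                 ent$surface[i]) {
        flag(s$id, "entity_surface",
             paste0(ent$id[i], " surface mismatch"))
      }
    }
    unknown <- setdiff(unique(c(s$pairs$e1, s$pairs$e2)), ent$id)
    if (length(unknown) > 0) {
      flag(s$id, "pair_ref", paste("unknown entity:",
                                   paste(unknown, collapse = ",")))
    }
    if (nrow(s$pairs) > 0) {
      key <- apply(s$pairs[, c("e1", "e2"), drop = FALSE], 1,
                   function(r) paste(sort(r), collapse = "|"))
      if (anyDuplicated(key)) flag(s$id, "pair_dup", "duplicate pair")
    }
    if (!is.na(s$parse)) {
      if (!ptb_check_balanced(s$parse)) {
        flag(s$id, "parse_brackets", "unbalanced parse")
      } else {
        leaves <- ptb_leaves(ptb_parse(s$parse))
        if (!identical(leaves, s$tokens$token)) {
          flag(s$id, "parse_tokens", "parse leaves != tokens")
        }
      }
    }
  }
  if (length(bad) == 0) {
    data.frame(sentence_id = character(0), check = character(0),
               message = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, bad)
  }
}
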