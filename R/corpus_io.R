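# Reader/writer for the unified PPI XML corpus dialect
# (corpus/document/sentence/entity/pair) and candidate-pair construction
# with entity blinding. Entity charOffsets are inclusive in the XML and
# converted to 0-based half-open intervals at this boundary only.

#' Read a unified PPI XML corpus
#'
#' Parses the unified corpus dialect used by the converted AIMed / BioInfer /
#' HPRD50 / IEPA / LLL releases: `corpus > document > sentence` with
#' `entity` children (inclusive `charOffset`, `text`) and `pair` children
#' (`e1`, `e2`, `interaction`). Inclusive character offsets become 0-based
#' half-open spans; `interaction="True"` becomes label `"positive"`.
#'
#' @param path Path to the XML file.
#' @return A `ppi_corpus`: list of `ppi_sentence` objects, each with `id`,
#'   `text`, `tokens` (data frame `token,start,end`), `entities`
#'   (data frame `id,start,end,surface`), `pairs` (data frame `e1,e2,label`)
#'   and `parse` (bracketed string or `NA`).
#' @export
read_ppi_xml <- function(path) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) stop("malformed XML in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  sentences <- list()
  for (snode in xml2::xml_find_all(doc, ".//sentence")) {
    sid <- xml2::xml_attr(snode, "id")
    text <- xml2::xml_attr(snode, "text")
    ents <- xml2::xml_find_all(snode, "./entity")
    entities <- data.frame(
      id = xml2::xml_attr(ents, "id"),
      start = integer(length(ents)),
      end = integer(length(ents)),
      surface = xml2::xml_attr(ents, "text"),
      stringsAsFactors = FALSE
    )
    if (length(ents) > 0) {
      offs <- xml2::xml_attr(ents, "charOffset")
      for (i in seq_along(offs)) {
        sp <- parse_char_offset(offs[i])
        entities$start[i] <- sp[1]
        entities$end[i] <- sp[2]
      }
    }
    bad <- entities$start < 0 | entities$end > nchar(text) |
      entities$start >= entities$end
    if (any(bad)) {
      stop("entity offset outside sentence bounds in sentence '", sid, "'")
    }
    spanned <- substring(text, entities$start + 1, entities$end)
    mism <- spanned != entities$surface
    if (any(mism)) {
      stop("entity surface does not match spanned text in sentence '", sid,
           "': ", paste(entities$id[mism], collapse = ", "))
    }
    prs <- xml2::xml_find_all(snode, "./pair")
    pairs <- data.frame(
      e1 = xml2::xml_attr(prs, "e1"),
      e2 = xml2::xml_attr(prs, "e2"),
      label = ifelse(tolower(xml2::xml_attr(prs, "interaction")) == "true",
                     "positive", "negative"),
      stringsAsFactors = FALSE
    )
    missing_ref <- setdiff(unique(c(pairs$e1, pairs$e2)), entities$id)
    if (length(missing_ref) > 0) {
      stop("pair references unknown entity id(s) in sentence '", sid, "': ",
           paste(missing_ref, collapse = ", "))
    }
    key <- apply(pairs[, c("e1", "e2"), drop = FALSE], 1,
                 function(r) paste(sort(r), collapse = "|"))
    if (anyDuplicated(key)) {
      stop("duplicate unordered pair in sentence '", sid, "'")
    }
    sentences[[length(sentences) + 1]] <- new_ppi_sentence(
      id = sid, text = text, entities = entities, pairs = pairs
    )
  }
  structure(sentences, class = "ppi_corpus",
            source = xml2::xml_attr(xml2::xml_root(doc), "source"))
}

# "a-b" (inclusive, 0-based) -> c(a, b+1). Discontinuous offsets
# ("a-b,c-d") are covered by their convex hull.
parse_char_offset <- function(off) {
  parts <- strsplit(off, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([0-9]+)-([0-9]+)$", parts))
  if (any(vapply(m, length, integer(1)) != 3L)) {
    stop("cannot parse charOffset '", off, "'")
  }
  starts <- vapply(m, function(x) as.integer(x[2]), integer(1))
  ends <- vapply(m, function(x) as.integer(x[3]), integer(1))
  c(min(starts), max(ends) + 1L)
}

new_ppi_sentence <- function(id, text, entities, pairs, parse = NA_character_) {
  structure(
    list(
      id = id, text = text,
      tokens = tokenize_sentence(text, entities),
      entities = entities, pairs = pairs, parse = parse
    ),
    class = "ppi_sentence"
  )
}

#' Tokenize sentence text, honouring entity boundaries
#'
#' Whitespace tokenization with entity span edges forced to token
#' boundaries; leading/trailing ASCII punctuation is peeled off tokens that
#' lie outside entity spans (so internal hyphens as in `IL-2` survive).
#' Token spans are 0-based half-open and never overlap.
#'
#' @param text Sentence text.
#' @param entities Optional data frame with `start`,`end` columns.
#' @return Data frame `token,start,end`.
#' @export
tokenize_sentence <- function(text, entities = NULL) {
  n <- nchar(text)
  if (n == 0) {
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  # Break positions (0-based, between chars): whitespace edges + entity edges.
  chars <- strsplit(text, "")[[1]]
  is_ws <- grepl("[[:space:]]", chars)
  breaks <- c(0L, n)
  if (!is.null(entities) && nrow(entities) > 0) {
    breaks <- c(breaks, entities$start, entities$end)
  }
  runs <- rle(is_ws)
  pos <- cumsum(runs$lengths)
  breaks <- sort(unique(c(breaks, pos[pos < n], 0L)))
  pieces <- data.frame(start = integer(0), end = integer(0))
  for (i in seq_len(length(breaks) - 1)) {
    s <- breaks[i]; e <- breaks[i + 1]
    if (all(is_ws[(s + 1):e])) next
    pieces <- rbind(pieces, data.frame(start = s, end = e))
  }
  covered <- function(s, e) {
    if (is.null(entities) || nrow(entities) == 0) return(FALSE)
    any(entities$start <= s & e <= entities$end)
  }
  out <- data.frame(token = character(0), start = integer(0),
                    end = integer(0), stringsAsFactors = FALSE)
  punct <- "[]\\[(){}.,;:!?\"']"
  for (i in seq_len(nrow(pieces))) {
    s <- pieces$start[i]; e <- pieces$end[i]
    if (covered(s, e)) {
      out <- rbind(out, data.frame(token = substring(text, s + 1, e),
                                   start = s, end = e,
                                   stringsAsFactors = FALSE))
      next
    }
    # Peel leading/trailing punctuation into their own tokens.
    lead <- integer(0)
    while (s < e && grepl(punct, substring(text, s + 1, s + 1))) {
      lead <- c(lead, s); s <- s + 1L
    }
    trail <- integer(0)
    while (e > s && grepl(punct, substring(text, e, e))) {
      trail <- c(e - 1L, trail); e <- e - 1L
    }
    for (p in lead) {
      out <- rbind(out, data.frame(token = substring(text, p + 1, p + 1),
                                   start = p, end = p + 1L,
                                   stringsAsFactors = FALSE))
    }
    if (e > s) {
      out <- rbind(out, data.frame(token = substring(text, s + 1, e),
                                   start = s, end = e,
                                   stringsAsFactors = FALSE))
    }
    for (p in trail) {
      out <- rbind(out, data.frame(token = substring(text, p + 1, p + 1),
                                   start = p, end = p + 1L,
                                   stringsAsFactors = FALSE))
    }
  }
  out[order(out$start), , drop = FALSE]
}

#' Write a corpus back to unified PPI XML
#' @param corpus A `ppi_corpus`.
#' @param path Output path.
#' @export
write_ppi_xml <- function(corpus, path) {
  root <- xml2::xml_new_root("corpus",
                             source = attr(corpus, "source") %||% "ppidstk")
  docnode <- xml2::xml_add_child(root, "document", id = "d1")
  for (s in corpus) {
    snode <- xml2::xml_add_child(docnode, "sentence", id = s$id, text = s$text)
    ent <- s$entities
    for (i in seq_len(nrow(ent))) {
      xml2::xml_add_child(
        snode, "entity", id = ent$id[i],
        charOffset = paste0(ent$start[i], "-", ent$end[i] - 1L),
        text = ent$surface[i], type = "protein"
      )
    }
    prs <- s$pairs
    for (i in seq_len(nrow(prs))) {
      xml2::xml_add_child(
        snode, "pair", id = paste0(s$id, ".p", i),
        e1 = prs$e1[i], e2 = prs$e2[i],
        interaction = ifelse(prs$label[i] == "positive", "True", "False")
      )
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Attach bracketed parses to a corpus
#'
#' Trees are aligned by `#id=` names when present, else by file order.
#' A count mismatch (order alignment) or an unknown id is fatal. Each
#' tree's leaves must equal the sentence's token sequence.
#'
#' @param corpus A `ppi_corpus`.
#' @param trees Character vector from [read_ptb_trees()].
#' @return The corpus with `parse` filled in.
#' @export
attach_parses <- function(corpus, trees) {
  if (is.null(names(trees))) {
    if (length(trees) != length(corpus)) {
      stop("tree/sentence count mismatch: ", length(trees), " trees vs ",
           length(corpus), " sentences")
    }
    idx <- seq_along(corpus)
    names(trees) <- vapply(corpus, `[[`, character(1), "id")
  }
  ids <- vapply(corpus, `[[`, character(1), "id")
  missing <- setdiff(ids, names(trees))
  if (length(missing) > 0) {
    stop("no parse tree for sentence(s): ", paste(missing, collapse = ", "))
  }
  for (i in seq_along(corpus)) {
    tr <- trees[[ids[i]]]
    leaves <- ptb_leaves(ptb_parse(tr))
    if (!identical(leaves, corpus[[i]]$tokens$token)) {
      stop("parse leaves do not match tokens for sentence '", ids[i], "'")
    }
    corpus[[i]]$parse <- tr
  }
  corpus
}

# Map each token to the entity covering it (longest span wins on overlap).
token_entity_map <- function(sentence) {
  toks <- sentence$tokens
  ents <- sentence$entities
  map <- rep(NA_character_, nrow(toks))
  if (nrow(ents) == 0) return(map)
  ord <- order(ents$end - ents$start)  # longest processed last, wins
  for (j in ord) {
    hit <- toks$start < ents$end[j] & toks$end > ents$start[j]
    if (any(!is.na(map[hit]) & map[hit] != ents$id[j])) {
      warning("overlapping entity mentions in sentence '", sentence$id,
              "'; keeping the longest span", call. = FALSE)
    }
    map[hit] <- ents$id[j]
  }
  map
}

#' Build blinded candidate instances for a sentence
#'
#' One instance per labelled pair: the two focus entities become single
#' `PROT1`/`PROT2` tokens (leftmost mention is `PROT1`), every other
#' entity collapses to `PROT`, multiword names collapse to one token.
#' Self-pairs are dropped with a warning. If the sentence carries a parse,
#' a consistently blinded tree accompanies each instance.
#'
#' @param sentence A `ppi_sentence`.
#' @return List of `ppi_instance` objects with fields `sentence_id`, `e1`,
#'   `e2`, `label`, `tokens` (blinded), `pos1`/`pos2` (indices of
#'   PROT1/PROT2), `e1_words`/`e2_words` (surface words of the focus
#'   names) and `parse` (blinded bracketed string or `NA`).
#' @export
make_instances <- function(sentence) {
  prs <- sentence$pairs
  if (nrow(prs) == 0) return(list())
  emap <- token_entity_map(sentence)
  ents <- sentence$entities
  out <- list()
  for (i in seq_len(nrow(prs))) {
    e1 <- prs$e1[i]; e2 <- prs$e2[i]
    if (e1 == e2) {
      warning("self-pair (", e1, ") in sentence '", sentence$id,
              "' dropped", call. = FALSE)
      next
    }
    # PROT1 is the leftmost mention of the pair.
    s1 <- ents$start[ents$id == e1]
    s2 <- ents$start[ents$id == e2]
    first <- if (s1 <= s2) e1 else e2
    second <- if (s1 <= s2) e2 else e1
    repl <- ifelse(is.na(emap), NA_character_,
                   ifelse(emap == first, "PROT1",
                          ifelse(emap == second, "PROT2", "PROT")))
    blind <- blind_token_runs(sentence$tokens$token, emap, repl)
    parse <- NA_character_
    if (!is.na(sentence$parse)) {
      parse <- blind_parse_tree(sentence$parse, sentence$tokens$token,
                                blind$action)
    }
    surf_words <- function(eid) {
      tolower(strsplit(ents$surface[ents$id == eid], "[[:space:]]+")[[1]])
    }
    out[[length(out) + 1]] <- structure(
      list(
        sentence_id = sentence$id, e1 = first, e2 = second,
        label = prs$label[i], tokens = blind$tokens,
        pos1 = match("PROT1", blind$tokens),
        pos2 = match("PROT2", blind$tokens),
        e1_words = surf_words(first), e2_words = surf_words(second),
        parse = parse
      ),
      class = "ppi_instance"
    )
  }
  out
}

# Collapse entity token runs to single blinded tokens. Returns the blinded
# token vector plus a per-original-token action ("keep", replacement
# symbol, or "drop") used to blind the parse tree identically.
blind_token_runs <- function(tokens, emap, repl) {
  n <- length(tokens)
  action <- rep("keep", n)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    if (is.na(emap[i])) {
      out <- c(out, tokens[i])
      i <- i + 1L
    } else {
      j <- i
      while (j < n && !is.na(emap[j + 1]) && emap[j + 1] == emap[i]) j <- j + 1L
      action[i] <- repl[i]
      if (j > i) action[(i + 1):j] <- "drop"
      out <- c(out, repl[i])
      i <- j + 1L
    }
  }
  list(tokens = out, action = action)
}

# Apply the per-token blinding actions to a bracketed parse whose leaves
# equal the original token sequence. Replaced leaves keep position but
# become NN preterminals; dropped leaves vanish with their preterminals,
# and internal nodes left childless are pruned.
blind_parse_tree <- function(parse, tokens, action) {
  tree <- ptb_parse(parse)
  leaves <- ptb_leaves(tree)
  if (length(leaves) != length(tokens) || !identical(leaves, tokens)) {
    stop("parse leaves do not match sentence tokens; cannot blind tree")
  }
  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  rec <- function(node) {
    if (ptb_is_preterminal(node)) {
      counter$i <- counter$i + 1L
      act <- action[counter$i]
      if (act == "keep") return(node)
      if (act == "drop") return(NULL)
      return(list(label = "NN", word = act))
    }
    kids <- Filter(Negate(is.null), lapply(node$children, rec))
    if (length(kids) == 0) return(NULL)
    list(label = node$label, children = kids)
  }
  blinded <- rec(tree)
  if (is.null(blinded)) stop("blinding removed the whole tree")
  ptb_format(blinded)
}

#' @export
print.ppi_corpus <- function(x, ...) {
  np <- sum(vapply(x, function(s) nrow(s$pairs), integer(1)))
  cat("ppi_corpus:", length(x), "sentences,", np, "candidate pairs\n")
  invisible(x)
}

#' @export
print.ppi_sentence <- function(x, ...) {
  cat("ppi_sentence", x$id, ":", x$text, "\n",
      nrow(x$entities), "entities,", nrow(x$pairs), "pairs\n")
  invisible(x)
}
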