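#' Parse a Penn-Treebank bracketed tree
#'
#' Parses one s-expression tree string into a nested node structure. A node
#' is a list with `label`, and either `word` (preterminal) or `children`
#' (internal node). Leaves are words attached to their preterminal.
#'
#' @param s A bracketed tree string, e.g.
#'   `"(S (NP (NN PROT1)) (VP (VBZ binds) (NP (NN PROT2))))"`.
#' @return A nested list of nodes.
#' @export
ptb_parse <- function(s) {
  toks <- ptb_lex(s)
  if (length(toks) == 0L) stop("empty tree string")
  pos <- 1L
  res <- ptb_parse_node(toks, pos)
  if (res$pos <= length(toks)) {
    stop("trailing content after tree at token ", res$pos)
  }
  res$node
}

ptb_lex <- function(s) {
  m <- gregexpr("\\(|\\)|[^()[:space:]]+", s)[[1]]
  if (m[1] == -1L) return(character(0))
  regmatches(s, list(m))[[1]]
}

ptb_parse_node <- function(toks, pos) {
  if (toks[pos] != "(") stop("expected '(' at token ", pos)
  pos <- pos + 1L
  if (pos > length(toks) || toks[pos] %in% c("(", ")")) {
    stop("expected node label at token ", pos)
  }
  label <- toks[pos]
  pos <- pos + 1L
  children <- list()
  words <- character(0)
  repeat {
    if (pos > length(toks)) stop("unbalanced brackets: unexpected end of input")
    tk <- toks[pos]
    if (tk == ")") {
      pos <- pos + 1L
      break
    }
    if (tk == "(") {
      res <- ptb_parse_node(toks, pos)
      children <- c(children, list(res$node))
      pos <- res$pos
    } else {
      words <- c(words, tk)
      pos <- pos + 1L
    }
  }
  if (length(words) > 0 && length(children) > 0) {
    stop("node '", label, "' mixes bare words and bracketed children")
  }
  if (length(words) > 1) {
    stop("preterminal '", label, "' carries more than one word")
  }
  node <- if (length(words) == 1) {
    list(label = label, word = words)
  } else if (length(children) > 0) {
    list(label = label, children = children)
  } else {
    stop("node '", label, "' has no children and no word")
  }
  list(node = node, pos = pos)
}

#' Format a tree node back to bracketed text
#' @param node A node from [ptb_parse()].
#' @return A single bracketed string.
#' @export
ptb_format <- function(node) {
  if (ptb_is_preterminal(node)) {
    paste0("(", node$label, " ", node$word, ")")
  } else {
    paste0("(", node$label, " ",
           paste(vapply(node$children, ptb_format, character(1)),
                 collapse = " "), ")")
  }
}

ptb_is_preterminal <- function(node) !is.null(node$word)

#' Leaf words of a bracketed tree, left to right
#' @param node A node from [ptb_parse()].
#' @return Character vector of leaf tokens.
#' @export
ptb_leaves <- function(node) {
  if (ptb_is_preterminal(node)) return(node$word)
  unlist(lapply(node$children, ptb_leaves), use.names = FALSE)
}

ptb_check_balanced <- function(s) {
  chars <- strsplit(s, "")[[1]]
  depth <- 0L
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(FALSE)
    }
  }
  depth == 0L
}

#' Read bracketed parse trees, one per record
#'
#' Records are non-empty lines; a line may start with `#id=<sentence_id>`
#' followed by whitespace and the tree, in which case trees are keyed by
#' sentence id, otherwise alignment is by file order.
#'
#' @param path Path to a UTF-8 text file of trees.
#' @return Named (if `#id=` used) character vector of validated tree strings.
#' @export
read_ptb_trees <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  ids <- rep(NA_character_, length(lines))
  trees <- character(length(lines))
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "#id=")) {
      sp <- regexpr("[[:space:]]", ln)
      if (sp == -1L) stop("line ", lineno[i], ": '#id=' record without a tree")
      ids[i] <- substr(ln, 5L, sp - 1L)
      ln <- trimws(substr(ln, sp + 1L, nchar(ln)))
    }
    if (!ptb_check_balanced(ln)) {
      stop("unbalanced brackets in tree at line ", lineno[i])
    }
    ptb_parse(ln)  # full structural validation
    trees[i] <- ln
  }
  if (all(!is.na(ids))) {
    names(trees) <- ids
  } else if (any(!is.na(ids))) {
    stop("mixed '#id=' and bare tree records; use one convention throughout")
  }
  trees
}

#' Write bracketed trees, one per line
#' @param trees Character vector of tree strings; names, if present, are
#'   written as `#id=` prefixes.
#' @param path Output path.
#' @export
write_ptb_trees <- function(trees, path) {
  out <- if (is.null(names(trees))) {
    trees
  } else {
    paste0("#id=", names(trees), "\t", trees)
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
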