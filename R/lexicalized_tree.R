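# Lexicalized constituency trees: every node carries a (syntactic label,
# head word) pair assigned by bottom-up head percolation, with an optional
# interaction-keyword override along the keyword's spine. Also hosts the
# exhaustive fragment enumerator and the exact smoothed tree kernel that
# serve as the brute-force oracle for the distributed approximation.

#' Read a head-rule table
#'
#' Text config, one rule per line: `PARENT direction priority-list`.
#' `direction` is `left` or `right` (child scan order). Parents without a
#' rule take their rightmost child as head.
#'
#' @param path File path; defaults to the bundled condensed Collins table.
#' @return Named list of `list(dir, priorities)` (class `head_rules`).
#' @export
read_head_rules <- function(path = system.file("extdata", "head_rules.txt",
                                               package = "ppidstk")) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  rules <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(parts) < 2 || !parts[2] %in% c("left", "right")) {
      stop("bad head rule line: '", ln, "'")
    }
    rules[[parts[1]]] <- list(dir = parts[2],
                              priorities = parts[-(1:2)])
  }
  structure(rules, class = "head_rules")
}

#' Default head-rule table
#' @return The bundled `head_rules` object.
#' @export
default_head_rules <- function() read_head_rules()

pick_head_child <- function(label, child_labels, rules) {
  rule <- rules[[label]]
  n <- length(child_labels)
  if (is.null(rule)) return(n)  # unknown category: rightmost child
  scan <- if (rule$dir == "left") seq_len(n) else rev(seq_len(n))
  for (cat in rule$priorities) {
    for (i in scan) if (child_labels[i] == cat) return(i)
  }
  scan[1]
}

#' Lexicalize a constituency tree
#'
#' Assigns every node its head word and head POS by bottom-up percolation
#' under `rules`. If `keyword_index` points at a leaf (1-based token
#' index), every node dominating that leaf has its head forced to the
#' keyword, so interaction verbs become the heads of their whole spine up
#' to the root.
#'
#' @param tree A bracketed string or a node from [ptb_parse()].
#' @param rules A `head_rules` table.
#' @param keyword_index Optional 1-based index of the (first) interaction
#'   keyword token; `NA` or empty for no override.
#' @param tokens Optional token vector the tree's leaves must equal.
#' @return A `lex_tree`: the annotated root plus flat per-node accessors.
#' @export
lexicalize <- function(tree, rules = default_head_rules(),
                       keyword_index = NA_integer_, tokens = NULL) {
  if (is.character(tree)) tree <- ptb_parse(tree)
  leaves <- ptb_leaves(tree)
  if (!is.null(tokens) && !identical(leaves, tokens)) {
    stop("tree leaves do not match the sentence tokens")
  }
  leaf_ctr <- new.env(parent = emptyenv()); leaf_ctr$i <- 0L
  annotate <- function(node) {
    if (ptb_is_preterminal(node)) {
      leaf_ctr$i <- leaf_ctr$i + 1L
      node$head_word <- node$word
      node$head_pos <- node$label
      node$leaf_lo <- leaf_ctr$i
      node$leaf_hi <- leaf_ctr$i
      return(node)
    }
    node$children <- lapply(node$children, annotate)
    labs <- vapply(node$children, `[[`, character(1), "label")
    h <- pick_head_child(node$label, labs, rules)
    node$head_child <- h
    node$head_word <- node$children[[h]]$head_word
    node$head_pos <- node$children[[h]]$head_pos
    node$leaf_lo <- node$children[[1]]$leaf_lo
    node$leaf_hi <- node$children[[length(node$children)]]$leaf_hi
    node
  }
  root <- annotate(tree)
  kw <- suppressWarnings(as.integer(keyword_index[1]))
  if (length(kw) == 1 && !is.na(kw)) {
    if (kw < 1 || kw > length(leaves)) {
      stop("keyword_index ", kw, " outside the leaf range 1..", length(leaves))
    }
    override <- function(node) {
      if (node$leaf_lo <= kw && kw <= node$leaf_hi &&
          !ptb_is_preterminal(node)) {
        node$head_word <- leaves[kw]
        # POS of the keyword's preterminal percolates with it.
        node$head_pos <- keyword_pos(node, kw)
        node$children <- lapply(node$children, override)
      }
      node
    }
    root <- override(root)
  }
  # Assign stable preorder ids.
  ctr <- new.env(parent = emptyenv()); ctr$i <- 0L
  number <- function(node) {
    ctr$i <- ctr$i + 1L
    node$nid <- ctr$i
    if (!ptb_is_preterminal(node)) {
      node$children <- lapply(node$children, number)
    }
    node
  }
  root <- number(root)
  structure(list(root = root, n_nodes = ctr$i, n_leaves = length(leaves)),
            class = "lex_tree")
}

keyword_pos <- function(node, kw) {
  if (ptb_is_preterminal(node)) return(node$label)
  for (ch in node$children) {
    if (ch$leaf_lo <= kw && kw <= ch$leaf_hi) return(keyword_pos(ch, kw))
  }
  node$head_pos
}

#' Flat node table of a lexicalized tree
#' @param t A `lex_tree`.
#' @return Data frame `id,label,head_word,head_pos,is_preterminal`.
#' @export
lex_nodes <- function(t) {
  rows <- list()
  walk <- function(node) {
    rows[[length(rows) + 1]] <<- data.frame(
      id = node$nid, label = node$label, head_word = node$head_word,
      head_pos = node$head_pos,
      is_preterminal = ptb_is_preterminal(node),
      stringsAsFactors = FALSE
    )
    if (!ptb_is_preterminal(node)) lapply(node$children, walk)
    invisible(NULL)
  }
  walk(t$root)
  do.call(rbind, rows)
}

#' Count subset-tree fragments without enumerating them
#'
#' Recursive product formula: a fragment rooted at an internal node keeps
#' all children, each either as a bare label or expanded into one of its
#' own fragments, so `f(n) = prod_c (1 + f(c))`; a preterminal always
#' expands to its word, `f = 1`. The total is the sum over all nodes.
#'
#' @param t A `lex_tree`.
#' @return List with `per_node` (named by node id) and `total`.
#' @export
count_fragments <- function(t) {
  per <- numeric(0)
  rec <- function(node) {
    if (ptb_is_preterminal(node)) {
      per[as.character(node$nid)] <<- 1
      return(1)
    }
    f <- prod(vapply(node$children, function(ch) 1 + rec(ch), numeric(1)))
    per[as.character(node$nid)] <<- f
    f
  }
  rec(t$root)
  list(per_node = per, total = sum(per))
}

#' Exhaustively enumerate subset-tree fragments
#'
#' Every fragment is a connected subgraph in which each included node
#' keeps all of its children or none; preterminals at the fragment root or
#' expanded inside it carry their word. Each fragment is returned with its
#' structural signature (bracketed string over labels and expanded words),
#' its production count `n_prod` (number of expanded nodes, the size that
#' enters the lambda decay) and the head word of its root node in the
#' source tree.
#'
#' @param t A `lex_tree`.
#' @param max_count Hard cap; exceeding it is an error (the enumerator is
#'   an oracle for small trees).
#' @return List of fragments: `root_id`, `sig`, `n_prod`, `head_word`.
#' @export
enumerate_fragments <- function(t, max_count = 10000) {
  total <- count_fragments(t)$total
  if (total > max_count) {
    stop("fragment count ", total, " exceeds max_count ", max_count)
  }
  out <- list()
  # Fragments rooted at `node`: list of list(sig, n_prod). Expanded
  # words carry a `w:` marker so a lexical leaf can never be confused
  # with a bare (un-expanded) child label of the same spelling.
  frags_rooted <- function(node) {
    if (ptb_is_preterminal(node)) {
      return(list(list(sig = paste0("(", node$label, " w:", node$word, ")"),
                       n_prod = 1L)))
    }
    child_opts <- lapply(node$children, function(ch) {
      c(list(list(sig = ch$label, n_prod = 0L)), frags_rooted(ch))
    })
    combos <- list(list(sig = character(0), n_prod = 0L))
    for (opts in child_opts) {
      nxt <- list()
      for (cmb in combos) {
        for (op in opts) {
          nxt[[length(nxt) + 1]] <- list(
            sig = c(cmb$sig, op$sig),
            n_prod = cmb$n_prod + op$n_prod
          )
        }
      }
      combos <- nxt
    }
    lapply(combos, function(cmb) {
      list(sig = paste0("(", node$label, " ",
                        paste(cmb$sig, collapse = " "), ")"),
           n_prod = cmb$n_prod + 1L)
    })
  }
  walk <- function(node) {
    for (fr in frags_rooted(node)) {
      out[[length(out) + 1]] <<- list(
        root_id = node$nid, sig = fr$sig, n_prod = fr$n_prod,
        head_word = node$head_word
      )
    }
    if (!ptb_is_preterminal(node)) lapply(node$children, walk)
    invisible(NULL)
  }
  walk(t$root)
  out
}

#' Exact smoothed tree kernel (brute-force oracle)
#'
#' Sum over all fragment pairs of
#' `lambda^((N_i+N_j)/2) * delta(frag_i, frag_j) * <v(head_i), v(head_j)>`
#' where `delta` is structural identity of the fragments (labels plus
#' expanded words), `N` counts expanded nodes, and head vectors are
#' unit-normalized embeddings (cosine semantics). Computed by grouping
#' fragments on their structural signature, which is exact.
#'
#' @param ta,tb `lex_tree` objects.
#' @param embeddings An `embedding_table` for head-word vectors.
#' @param lambda Decay in (0,1], default 0.4.
#' @param max_count Fragment cap per tree (oracle is for small trees).
#' @return Kernel value (symmetric in its tree arguments).
#' @export
exact_stk <- function(ta, tb, embeddings, lambda = 0.4, max_count = 10000) {
  stopifnot(lambda > 0, lambda <= 1)
  acc <- function(t) {
    frs <- enumerate_fragments(t, max_count)
    env <- new.env(parent = emptyenv())
    for (fr in frs) {
      v <- lambda^(fr$n_prod / 2) *
        embedding_lookup(embeddings, fr$head_word)
      if (is.null(env[[fr$sig]])) env[[fr$sig]] <- v
      else env[[fr$sig]] <- env[[fr$sig]] + v
    }
    env
  }
  ea <- acc(ta)
  eb <- acc(tb)
  total <- 0
  for (sig in ls(ea)) {
    vb <- eb[[sig]]
    if (!is.null(vb)) total <- total + sum(ea[[sig]] * vb)
  }
  total
}
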