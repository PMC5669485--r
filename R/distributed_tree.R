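# Distributed smoothed trees: each tree becomes a d x k matrix whose
# Frobenius inner products approximate the exact smoothed tree kernel.
# Structure is encoded with nearly orthogonal random label vectors
# composed by shuffled circular convolution; meaning enters through the
# distributional head-word vectors. The per-node recursion
#   s(n) = sqrt(lambda) * compose(r_label(n), z(c1) (*) ... (*) z(cm)),
#   z(c) = r_label(c) + s(c)
# expands, by bilinearity, to the explicit sum over all fragments rooted
# at n of lambda^(N(f)/2) * phi(f), which the tests verify against the
# brute-force enumerator.

#' Create a random label-vector store
#'
#' Vectors are uniform on the unit sphere (i.i.d. Gaussian components,
#' normalized to exactly unit length) and are
#' generated lazily and memoized, keyed by a namespace (`syn` for
#' syntactic labels, `word` for leaf words) and the label. The same
#' (seed, label) always yields the same vector. The store also fixes the
#' single random permutation used by [compose_vectors()].
#'
#' @param d Structural dimension (default 4096).
#' @param seed Master seed (default 42).
#' @return A `label_store`.
#' @export
new_label_store <- function(d = 4096L, seed = 42L) {
  d <- as.integer(d)
  perm <- with_seed(derive_seed(seed, "permutation"), sample.int(d))
  structure(
    list(d = d, seed = seed, perm = perm,
         cache = new.env(parent = emptyenv())),
    class = "label_store"
  )
}

#' Fetch the random vector of a label
#' @param store A `label_store`.
#' @param kind Namespace, `"syn"` or `"word"`.
#' @param label Label string.
#' @return Numeric vector of length `store$d`.
#' @export
label_vector <- function(store, kind = c("syn", "word"), label) {
  kind <- match.arg(kind)
  key <- paste0(kind, ":", label)
  v <- store$cache[[key]]
  if (is.null(v)) {
    v <- with_seed(derive_seed(store$seed, key), stats::rnorm(store$d))
    v <- v / sqrt(sum(v^2))  # exactly unit norm (spherical)
    store$cache[[key]] <- v
  }
  v
}

#' Shuffled circular convolution
#'
#' `compose(a, b) = circconv(perm(a), b)`, computed via FFT. Bilinear,
#' non-commutative, and approximately norm-preserving for random unit
#' inputs; distinct compositions of random vectors stay nearly orthogonal,
#' which is what lets fragment dot products approximate the Kronecker
#' delta.
#'
#' @param a,b Numeric vectors of equal length `d`.
#' @param store A `label_store` supplying the fixed permutation (or a
#'   bare integer permutation).
#' @return Numeric vector of length `d`.
#' @export
compose_vectors <- function(a, b, store) {
  if (length(a) != length(b)) {
    stop("dimension mismatch: ", length(a), " vs ", length(b))
  }
  perm <- if (inherits(store, "label_store")) store$perm else store
  if (length(perm) != length(a)) {
    stop("permutation length ", length(perm), " does not match d = ",
         length(a))
  }
  d <- length(a)
  Re(stats::fft(stats::fft(a[perm]) * stats::fft(b), inverse = TRUE)) / d
}

#' Distributed encoding of one fragment
#'
#' Encodes a fragment signature (as produced by [enumerate_fragments()])
#' into R^d: an expanded node contributes
#' `sqrt(lambda) * compose(r_label, fold of child encodings)`, an
#' un-expanded child its bare label vector, an expanded preterminal
#' `sqrt(lambda) * compose(r_pos, r_word)`. The returned vector therefore
#' already carries the fragment's weight `lambda^(N(f)/2)`.
#'
#' @param sig Fragment signature string.
#' @param store A `label_store`.
#' @param lambda Decay in (0,1].
#' @return Numeric vector of length `store$d`.
#' @export
fragment_embedding <- function(sig, store, lambda = 0.4) {
  rec <- function(nd) {
    if (!is.null(nd$word)) {       # expanded preterminal
      return(sqrt(lambda) *
               compose_vectors(label_vector(store, "syn", nd$label),
                               label_vector(store, "word", nd$word),
                               store))
    }
    if (is.null(nd$children)) {    # bare (un-expanded) child label
      return(label_vector(store, "syn", nd$label))
    }
    encs <- lapply(nd$children, rec)
    acc <- encs[[1]]
    for (e in encs[-1]) acc <- compose_vectors(acc, e, store)
    sqrt(lambda) * compose_vectors(label_vector(store, "syn", nd$label),
                                   acc, store)
  }
  rec(parse_sig(sig))
}

# Signature parser: atoms are bare labels (un-expanded children) or
# `w:`-prefixed leaf words; `(POS w:word)` is an expanded preterminal.
parse_sig <- function(s) {
  toks <- ptb_lex(s)
  pos <- new.env(parent = emptyenv()); pos$i <- 1L
  rec <- function() {
    tk <- toks[pos$i]
    if (tk != "(") {
      pos$i <- pos$i + 1L
      return(list(label = tk))
    }
    pos$i <- pos$i + 1L
    label <- toks[pos$i]; pos$i <- pos$i + 1L
    kids <- list()
    while (toks[pos$i] != ")") kids[[length(kids) + 1]] <- rec()
    pos$i <- pos$i + 1L
    if (length(kids) == 1 && is.null(kids[[1]]$children) &&
        startsWith(kids[[1]]$label, "w:")) {
      return(list(label = label, word = substring(kids[[1]]$label, 3)))
    }
    list(label = label, children = kids)
  }
  rec()
}

# Per-node structural vectors s(n) for a lexicalized tree, with head
# words, via the fragment-sum recursion.
dst_node_vectors <- function(t, store, lambda = 0.4) {
  ids <- integer(0); heads <- character(0)
  S <- list()
  rec <- function(node) {
    if (ptb_is_preterminal(node)) {
      s <- sqrt(lambda) *
        compose_vectors(label_vector(store, "syn", node$label),
                        label_vector(store, "word", node$word), store)
    } else {
      zs <- lapply(node$children, function(ch) {
        label_vector(store, "syn", ch$label) + rec(ch)
      })
      acc <- zs[[1]]
      for (z in zs[-1]) acc <- compose_vectors(acc, z, store)
      s <- sqrt(lambda) *
        compose_vectors(label_vector(store, "syn", node$label), acc, store)
    }
    ids <<- c(ids, node$nid)
    heads <<- c(heads, node$head_word)
    S[[length(S) + 1]] <<- s
    s
  }
  rec(t$root)
  list(ids = ids, heads = heads, S = do.call(cbind, S))
}

#' Distributed smoothed tree matrix
#'
#' `T = sum_n s(n) v(w_n)^T`, with `s(n)` the structural sum over all
#' fragments rooted at `n` and `v(w_n)` the unit-normalized distributional
#' vector of the node's head word (grouping by root node is valid because
#' all fragments rooted at `n` share its head word). The Frobenius
#' product of two such matrices approximates [exact_stk()].
#'
#' @param t A `lex_tree`.
#' @param store A `label_store`.
#' @param embeddings An `embedding_table`.
#' @param lambda Decay in (0,1], default 0.4.
#' @return A `dst_matrix`: list with `matrix` (d x k), `d`, `k`, `lambda`,
#'   `seed`.
#' @export
dst_matrix <- function(t, store, embeddings, lambda = 0.4) {
  nv <- dst_node_vectors(t, store, lambda)
  V <- t(vapply(nv$heads, function(w) embedding_lookup(embeddings, w),
                numeric(embeddings$k)))
  Tm <- nv$S %*% V
  structure(list(matrix = Tm, d = store$d, k = embeddings$k,
                 lambda = lambda, seed = store$seed),
            class = "dst_matrix")
}

#' Distributed smoothed tree kernel (Frobenius product)
#' @param Ta,Tb `dst_matrix` objects of matching shape.
#' @return Kernel value.
#' @export
dstk <- function(Ta, Tb) {
  if (Ta$d != Tb$d || Ta$k != Tb$k) {
    stop("shape mismatch: (", Ta$d, ",", Ta$k, ") vs (", Tb$d, ",", Tb$k, ")")
  }
  sum(Ta$matrix * Tb$matrix)
}
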