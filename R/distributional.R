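# Distributional head-word vectors: sentence-scope co-occurrence counts,
# positive PMI weighting and truncated SVD. Vectors are unit-normalized at
# lookup time so the smoothed kernel's semantic factor is a cosine.

#' Count token co-occurrences
#'
#' Every ordered pair of distinct token positions within scope contributes
#' one count, so the matrix is symmetric and repeated tokens are counted
#' per occurrence pair. Scope is the whole sentence (default) or a
#' +/- `window` token window.
#'
#' @param token_lists List of character vectors (one per sentence),
#'   already normalized.
#' @param scope `"sentence"` or `"window"`.
#' @param window Window half-width when `scope = "window"`.
#' @return A `cooc_counts`: list with `counts` (square matrix with vocab
#'   dimnames), `vocab`, `total`.
#' @export
count_cooccurrences <- function(token_lists, scope = c("sentence", "window"),
                                window = 5L) {
  scope <- match.arg(scope)
  token_lists <- Filter(length, token_lists)
  if (length(token_lists) == 0) stop("empty corpus: no tokens to count")
  vocab <- sort(unique(unlist(token_lists, use.names = FALSE)))
  V <- length(vocab)
  C <- matrix(0, V, V, dimnames = list(vocab, vocab))
  for (toks in token_lists) {
    idx <- match(toks, vocab)
    n <- length(idx)
    if (n < 2) next
    if (scope == "sentence") {
      cnt <- tabulate(idx, nbins = V)
      C <- C + outer(cnt, cnt)
      diag(C)[unique(idx)] <- diag(C)[unique(idx)] -
        cnt[unique(idx)]  # remove i == j self pairs
    } else {
      for (i in seq_len(n)) {
        lo <- max(1L, i - window); hi <- min(n, i + window)
        for (j in lo:hi) {
          if (j != i) C[idx[i], idx[j]] <- C[idx[i], idx[j]] + 1
        }
      }
    }
  }
  structure(list(counts = C, vocab = vocab, total = sum(C)),
            class = "cooc_counts")
}

#' Positive pointwise mutual information weighting
#'
#' `ppmi(w,c) = max(0, log(p(w,c) / (p(w) p(c))))` with probabilities from
#' the count matrix; cells with zero counts stay 0 (the clipped variant is
#' total where plain PMI is undefined).
#'
#' @param C A `cooc_counts` or a non-negative count matrix.
#' @return Real matrix of the same shape, elementwise non-negative.
#' @export
pmi_weight <- function(C) {
  M <- if (inherits(C, "cooc_counts")) C$counts else C
  total <- sum(M)
  if (total <= 0) stop("total co-occurrence count must be positive")
  pw <- rowSums(M) / total
  pc <- colSums(M) / total
  P <- M / total
  denom <- outer(pw, pc)
  out <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
  nz <- M > 0 & denom > 0
  out[nz] <- log(P[nz] / denom[nz])
  out[out < 0] <- 0
  out
}

#' Reduce a weighted matrix to k-dimensional word vectors by SVD
#'
#' Word vectors are the rows of `U_k Sigma_k`. The decomposition is made
#' deterministic up to reruns by fixing each singular vector's sign so its
#' largest-magnitude component is positive.
#'
#' @param M Real matrix (rows = target words; rownames used as vocabulary).
#' @param k Target dimension, `k <= min(dim(M))`.
#' @param oov Out-of-vocabulary policy for the resulting table: `"zero"`
#'   or `"hash"`.
#' @return An `embedding_table`.
#' @export
svd_reduce <- function(M, k, oov = c("zero", "hash")) {
  oov <- match.arg(oov)
  if (k > min(dim(M))) {
    stop("k = ", k, " exceeds min(dim(M)) = ", min(dim(M)))
  }
  dec <- svd(M, nu = k, nv = 0)
  U <- dec$u
  for (j in seq_len(k)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  vec <- U %*% diag(dec$d[seq_len(k)], k, k)
  rownames(vec) <- rownames(M)
  embedding_table(vec, oov = oov)
}

#' Construct an embedding table
#'
#' @param vectors Numeric matrix, one row per word (rownames required).
#' @param oov `"zero"` (unknown words get the zero vector, contributing no
#'   semantic mass) or `"hash"` (deterministic pseudo-random unit vector
#'   derived from the word and `hash_seed`).
#' @param hash_seed Seed for the hash policy.
#' @return An `embedding_table`: list `vectors`, `k`, `oov`, `hash_seed`.
#' @export
embedding_table <- function(vectors, oov = c("zero", "hash"),
                            hash_seed = 1L) {
  oov <- match.arg(oov)
  if (is.null(rownames(vectors))) stop("vectors must have word rownames")
  if (any(!is.finite(vectors))) stop("embedding vectors must be finite")
  structure(list(vectors = vectors, k = ncol(vectors), oov = oov,
                 hash_seed = as.integer(hash_seed)),
            class = "embedding_table")
}

#' Look up a (unit-normalized) word vector
#'
#' Blinded focus placeholders `PROT1`/`PROT2` fall back to the generic
#' `PROT` row when absent, so all blinded proteins share one vector.
#' Unknown words follow the table's OOV policy; the hash policy returns
#' the same vector for the same word on every call.
#'
#' @param E An `embedding_table`.
#' @param word Single word.
#' @param normalize Unit-normalize before returning (default TRUE).
#' @return Numeric vector of length `E$k`.
#' @export
embedding_lookup <- function(E, word, normalize = TRUE) {
  w <- word
  if (!w %in% rownames(E$vectors) && w %in% c("PROT1", "PROT2") &&
      "PROT" %in% rownames(E$vectors)) {
    w <- "PROT"
  }
  if (w %in% rownames(E$vectors)) {
    v <- E$vectors[w, ]
  } else if (E$oov == "zero") {
    return(numeric(E$k))
  } else {
    v <- with_seed(derive_seed(E$hash_seed, paste0("oov:", word)),
                   stats::rnorm(E$k))
  }
  if (normalize) unit_vec(v) else v
}

#' Build head-word embeddings from a corpus
#'
#' The pipeline's default vector source: sentences are normalized, every
#' entity mention collapses to the generic `PROT` token (so blinded trees
#' find a protein vector), sentence-scope co-occurrences are PPMI-weighted
#' and reduced by SVD. `k` is capped at the matrix rank bound
#' `min(dim)`, since a small corpus cannot support the full default
#' dimension.
#'
#' @param corpus A `ppi_corpus`.
#' @param k Requested dimension (default 1024; 2048 is the other standard
#'   choice).
#' @param oov OOV policy for the table.
#' @return An `embedding_table`.
#' @export
build_embeddings <- function(corpus, k = 1024L, oov = c("zero", "hash")) {
  oov <- match.arg(oov)
  token_lists <- lapply(corpus, function(s) {
    emap <- token_entity_map(s)
    toks <- s$tokens$token
    # collapse each entity run to one PROT token
    out <- character(0)
    i <- 1L
    while (i <= length(toks)) {
      if (is.na(emap[i])) {
        out <- c(out, toks[i]); i <- i + 1L
      } else {
        j <- i
        while (j < length(toks) && !is.na(emap[j + 1]) &&
               emap[j + 1] == emap[i]) j <- j + 1L
        out <- c(out, "PROT")
        i <- j + 1L
      }
    }
    normalize_tokens(out)
  })
  C <- count_cooccurrences(token_lists, scope = "sentence")
  M <- pmi_weight(C)
  k_eff <- min(as.integer(k), min(dim(M)))
  svd_reduce(M, k_eff, oov = oov)
}

#' Write an embedding table in word2vec text format
#'
#' Header line `vocab_size k`, then one `word v1 ... vk` line per word.
#'
#' @param E An `embedding_table`.
#' @param path Output path.
#' @export
write_embeddings <- function(E, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(E$vectors), E$k), con)
  words <- rownames(E$vectors)
  for (i in seq_len(nrow(E$vectors))) {
    writeLines(paste(c(words[i],
                       format(E$vectors[i, ], trim = TRUE, digits = 17,
                              scientific = TRUE)),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read a word2vec-style text embedding table
#' @param path Input path.
#' @param oov OOV policy to attach.
#' @return An `embedding_table`.
#' @export
read_embeddings <- function(path, oov = c("zero", "hash")) {
  oov <- match.arg(oov)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  hdr <- as.integer(strsplit(trimws(lines[1]), "[[:space:]]+")[[1]])
  if (length(hdr) != 2 || any(is.na(hdr))) {
    stop("expected 'vocab_size k' header in '", path, "'")
  }
  n <- hdr[1]; k <- hdr[2]
  if (length(lines) < n + 1) stop("embedding file truncated")
  words <- character(n)
  vec <- matrix(0, n, k)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1]), "[[:space:]]+")[[1]]
    if (length(parts) != k + 1) {
      stop("embedding row ", i, " has ", length(parts) - 1,
           " components, expected ", k)
    }
    words[i] <- parts[1]
    vec[i, ] <- as.numeric(parts[-1])
  }
  rownames(vec) <- words
  embedding_table(vec, oov = oov)
}
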