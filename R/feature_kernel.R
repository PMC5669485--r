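# Feature-based kernel: lexical word features and inter-entity word
# distance features over blinded candidate instances, combined by a plain
# linear (inner-product) kernel. Sparse vectors are named numeric vectors
# with namespaced feature names (P-, p-, b-, l-, r-, ik-, dist-bin,
# protcount); zero-valued entries are never stored.

#' Word features of a candidate instance
#'
#' Binary features: `P-`/`p-` prefixed lowercased surface words of the
#' first/second (leftmost/rightmost) protein name; `b-` every normalized
#' token strictly between the two focus entities; `l-` up to 3 tokens left
#' of the first entity and `r-` up to 3 tokens right of the second; `ik-`
#' the lemma of the first interaction keyword in the sentence, if any.
#' Blinded `PROT*` placeholders never generate b-/l-/r- features; protein
#' names enter only through the `P-`/`p-` surface-word channel.
#'
#' @param instance A `ppi_instance` from [make_instances()].
#' @param lexicon Interaction lexicon.
#' @param window Context window width in tokens (default 3).
#' @return Named numeric sparse feature vector.
#' @export
extract_word_features <- function(instance, lexicon = default_lexicon(),
                                  window = 3L) {
  toks <- normalize_tokens(instance$tokens)
  tagged <- pos_lemma(toks, lexicon)
  i1 <- min(instance$pos1, instance$pos2)
  i2 <- max(instance$pos1, instance$pos2)
  pre <- function(prefix, xs) {
    if (length(xs) == 0) character(0) else paste0(prefix, xs)
  }
  feats <- c(pre("P-", instance$e1_words), pre("p-", instance$e2_words))
  between <- if (i2 - i1 > 1) toks[(i1 + 1):(i2 - 1)] else character(0)
  feats <- c(feats, pre("b-", between[!is_blinded_token(between)]))
  left <- if (i1 > 1) toks[max(1, i1 - window):(i1 - 1)] else character(0)
  feats <- c(feats, pre("l-", left[!is_blinded_token(left)]))
  n <- length(toks)
  right <- if (i2 < n) toks[(i2 + 1):min(n, i2 + window)] else character(0)
  feats <- c(feats, pre("r-", right[!is_blinded_token(right)]))
  kw <- find_interaction_keywords(tagged, lexicon)
  if (length(kw) > 0) feats <- c(feats, paste0("ik-", tagged$lemma[kw[1]]))
  v <- rep(1, length(unique(feats)))
  names(v) <- unique(feats)
  v
}

#' Inter-entity distance counts
#'
#' Counts tokens strictly between the two focus placeholders, split into
#' non-protein words and blinded `PROT` distractors, and maps the
#' non-protein count to its bin: 0 tokens -> 0, count < 3 -> 1,
#' count in \[3,6) -> 2, count in \[6,9) -> 3, otherwise 4.
#'
#' @param instance A `ppi_instance`.
#' @return List with `nonprot`, `nprot` and `bin`.
#' @export
distance_counts <- function(instance) {
  i1 <- min(instance$pos1, instance$pos2)
  i2 <- max(instance$pos1, instance$pos2)
  between <- if (i2 - i1 > 1) instance$tokens[(i1 + 1):(i2 - 1)] else character(0)
  nprot <- sum(between == "PROT")
  nonprot <- length(between) - nprot
  bin <- distance_bin(nonprot, n_between = length(between))
  list(nonprot = nonprot, nprot = nprot, bin = bin)
}

# Bin rule for the non-protein word count. "No tokens at all between the
# pair" is bin 0; the count bins are half-open so every count maps to
# exactly one bin.
distance_bin <- function(nonprot, n_between = nonprot) {
  if (n_between == 0) 0L
  else if (nonprot < 3) 1L
  else if (nonprot < 6) 2L
  else if (nonprot < 9) 3L
  else 4L
}

#' Distance features of a candidate instance
#'
#' Numeric features `dist-bin` (the bin of [distance_counts()]) and
#' `protcount` (number of blinded distractor proteins between the pair).
#' Zero values are omitted from the sparse vector.
#'
#' @param instance A `ppi_instance`.
#' @return Named numeric sparse feature vector.
#' @export
extract_distance_features <- function(instance) {
  dc <- distance_counts(instance)
  v <- c("dist-bin" = as.numeric(dc$bin), "protcount" = as.numeric(dc$nprot))
  v[v != 0]
}

#' Full feature vector (word + distance features)
#' @inheritParams extract_word_features
#' @return Named numeric sparse feature vector.
#' @export
extract_features <- function(instance, lexicon = default_lexicon(),
                             window = 3L) {
  c(extract_word_features(instance, lexicon, window),
    extract_distance_features(instance))
}

#' Linear kernel between sparse feature vectors
#' @param v1,v2 Named numeric vectors.
#' @return Inner product over shared feature names.
#' @export
linear_kernel <- function(v1, v2) {
  common <- intersect(names(v1), names(v2))
  if (length(common) == 0) return(0)
  sum(v1[common] * v2[common])
}

# Dense Gram matrix over a list of sparse feature vectors via a shared
# feature index (BLAS crossproduct; equivalent to pairwise linear_kernel).
feature_gram <- function(vectors) {
  all_names <- unique(unlist(lapply(vectors, names), use.names = FALSE))
  n <- length(vectors)
  X <- matrix(0, n, length(all_names), dimnames = list(NULL, all_names))
  for (i in seq_len(n)) X[i, names(vectors[[i]])] <- vectors[[i]]
  tcrossprod(X)
}

#' Write feature vectors in sparse text format
#'
#' One line per instance: `instance_id \t name:value \t ...`.
#'
#' @param vectors Named list of sparse feature vectors.
#' @param path Output path.
#' @export
write_feature_file <- function(vectors, path) {
  ids <- names(vectors) %||% as.character(seq_along(vectors))
  lines <- vapply(seq_along(vectors), function(i) {
    v <- vectors[[i]]
    kv <- if (length(v) == 0) character(0) else {
      paste0(names(v), ":", format(v, trim = TRUE, scientific = FALSE))
    }
    paste(c(ids[i], kv), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read feature vectors written by [write_feature_file()]
#' @param path Input path.
#' @return Named list of sparse feature vectors.
#' @export
read_feature_file <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    id <- parts[1]
    if (length(parts) > 1) {
      kv <- strsplit(parts[-1], ":", fixed = TRUE)
      v <- vapply(kv, function(x) as.numeric(x[length(x)]), numeric(1))
      names(v) <- vapply(kv, function(x)
        paste(x[-length(x)], collapse = ":"), character(1))
    } else {
      v <- numeric(0)
    }
    out[[id]] <- v
  }
  out
}
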