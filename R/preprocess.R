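# Token normalization, rule-based POS/lemma tagging and interaction
# keyword detection. Tagging is a pluggable contract: any backend that
# returns one POS tag and one lemma per token can stand behind
# pos_lemma(); the bundled rule-based tagger keeps the pipeline
# self-contained and offline.

#' Normalize tokens
#'
#' Lowercases alphabetic characters and replaces tokens that are entirely
#' numeric (optionally signed integers or decimals) with the sentinel
#' `NUM`. Blinded placeholders `PROT1`/`PROT2`/`PROT` pass through
#' unchanged. Alphanumeric identifiers such as `IL-2` are not numbers and
#' are only lowercased. Idempotent.
#'
#' @param tokens Character vector.
#' @return Character vector of the same length.
#' @export
normalize_tokens <- function(tokens) {
  if (length(tokens) == 0) return(character(0))
  out <- tokens
  blind <- is_blinded_token(tokens) | tokens == "NUM"
  numeric_tok <- grepl("^[+-]?([0-9]+([.][0-9]*)?|[.][0-9]+)$", tokens)
  out[numeric_tok & !blind] <- "NUM"
  idx <- !numeric_tok & !blind
  out[idx] <- tolower(tokens[idx])
  out
}

#' Read an interaction keyword lexicon
#'
#' Plain text, one lowercase lemma per line, `#` starts a comment.
#'
#' @param path File path; defaults to the bundled biomedical interaction
#'   verb lexicon.
#' @return Character vector of lemmas (class `interaction_lexicon`).
#' @export
read_lexicon <- function(path = system.file("extdata",
                                            "interaction_lexicon.txt",
                                            package = "ppidstk")) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty interaction lexicon: ", path)
  if (any(grepl("[[:space:]]", lines))) {
    stop("lexicon entries must not contain whitespace")
  }
  structure(unique(tolower(lines)), class = "interaction_lexicon")
}

#' Default interaction keyword lexicon
#' @return The bundled lexicon (see [read_lexicon()]).
#' @export
default_lexicon <- function() read_lexicon()

# Suffix-stripping lemmatizer with vocabulary-assisted stem repair. The
# vocabulary (normally the interaction lexicon) is used to confirm
# candidate stems, e.g. "binding" -> "bind", "associates" -> "associate",
# "interaction" -> "interact".
lemmatize_token <- function(word, vocab = character(0)) {
  if (word %in% c(BLINDED_TOKENS, "NUM")) return(word)
  if (word %in% vocab) return(word)
  in_vocab <- function(w) length(w) == 1 && w %in% vocab
  cands <- character(0)
  add <- function(w) if (nchar(w) >= 2) cands <<- c(cands, w)
  nc <- nchar(word)
  suf <- function(k) substring(word, nc - k + 1, nc)
  stem <- function(k) substring(word, 1, nc - k)
  if (nc > 3 && suf(3) == "ies") add(paste0(stem(3), "y"))
  if (nc > 4 && suf(4) == "sses") add(stem(2))
  if (nc > 3 && suf(2) == "es") { add(stem(1)); add(stem(2)) }
  if (nc > 2 && suf(1) == "s" && !suf(2) %in% c("ss", "us", "is")) add(stem(1))
  if (nc > 4 && suf(3) == "ing") {
    st <- stem(3)
    add(st); add(paste0(st, "e"))
    if (nchar(st) > 2 && substring(st, nchar(st), nchar(st)) ==
        substring(st, nchar(st) - 1, nchar(st) - 1)) {
      add(substring(st, 1, nchar(st) - 1))
    }
  }
  if (nc > 4 && suf(3) == "ied") add(paste0(stem(3), "y"))
  if (nc > 3 && suf(2) == "ed") {
    add(stem(1)); add(stem(2))
    st <- stem(2)
    if (nchar(st) > 2 && substring(st, nchar(st), nchar(st)) ==
        substring(st, nchar(st) - 1, nchar(st) - 1)) {
      add(substring(st, 1, nchar(st) - 1))
    }
  }
  if (nc > 4 && suf(3) == "ion") { add(stem(3)); add(paste0(stem(3), "e")) }
  if (nc > 5 && suf(4) == "ions") { add(stem(4)); add(paste0(stem(4), "e")) }
  for (cd in cands) if (in_vocab(cd)) return(cd)
  # No vocabulary confirmation: apply conservative plural/inflection rules.
  if (nc > 3 && suf(3) == "ies") return(paste0(stem(3), "y"))
  if (nc > 2 && suf(1) == "s" && !suf(2) %in% c("ss", "us", "is")) {
    if (nc > 3 && suf(2) == "es" &&
        substring(word, nc - 3, nc - 2) %in% c("ch", "sh") ||
        (nc > 3 && substring(word, nc - 2, nc - 2) %in% c("x", "z"))) {
      return(stem(2))
    }
    return(stem(1))
  }
  if (nc > 4 && suf(3) == "ing") return(stem(3))
  word
}

# Closed-class POS table for the rule-based tagger.
FUNCTION_POS <- c(
  the = "DT", a = "DT", an = "DT", these = "DT", this = "DT", that = "IN",
  and = "CC", or = "CC", but = "CC",
  of = "IN", "in" = "IN", by = "IN", with = "IN", from = "IN", to = "TO",
  on = "IN", at = "IN", "for" = "IN", whereas = "IN", into = "IN",
  was = "VBD", were = "VBD", is = "VBZ", are = "VBP", be = "VB",
  been = "VBN", not = "RB", also = "RB"
)

#' POS-tag and lemmatize normalized tokens
#'
#' Bundled rule-based backend: closed-class lookup, suffix heuristics for
#' open-class tags, and the suffix-stripping lemmatizer with
#' vocabulary-assisted repair against `lexicon`. Guarantees exactly one
#' tag and one lemma per token.
#'
#' @param tokens Normalized token vector (see [normalize_tokens()]).
#' @param lexicon Interaction lexicon used to confirm candidate lemmas.
#' @return Data frame `token,pos,lemma`.
#' @export
pos_lemma <- function(tokens, lexicon = default_lexicon()) {
  n <- length(tokens)
  pos <- character(n)
  lemma <- character(n)
  for (i in seq_len(n)) {
    w <- tokens[i]
    lemma[i] <- lemmatize_token(w, lexicon)
    pos[i] <- if (is_blinded_token(w)) "NN"
    else if (w == "NUM") "CD"
    else if (grepl("^[[:punct:]]+$", w)) w
    else if (!is.na(FUNCTION_POS[w])) unname(FUNCTION_POS[w])
    else if (lemma[i] %in% lexicon) {
      if (grepl("s$", w) && !grepl("s$", lemma[i])) "VBZ"
      else if (grepl("ing$", w)) "VBG"
      else if (grepl("ed$", w)) "VBN"
      else if (grepl("ion s?$|ions$", w)) "NN"
      else "VB"
    }
    else if (grepl("ly$", w)) "RB"
    else if (grepl("ing$", w)) "VBG"
    else if (grepl("ed$", w)) "VBN"
    else if (grepl("s$", w) && !grepl("ss$|us$|is$", w)) "NNS"
    else "NN"
  }
  data.frame(token = tokens, pos = pos, lemma = lemma,
             stringsAsFactors = FALSE)
}

#' Locate interaction keywords
#'
#' Indices (ascending) of tokens whose lemma is in the lexicon. Callers
#' use the first index for the `ik-` feature and for the head-word
#' override of the lexicalized tree.
#'
#' @param tagged Data frame from [pos_lemma()].
#' @param lexicon An `interaction_lexicon`.
#' @return Integer vector of 1-based token indices.
#' @export
find_interaction_keywords <- function(tagged, lexicon = default_lexicon()) {
  which(tagged$lemma %in% lexicon)
}
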