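# Sub-token SMILES vocabulary: syntactic base units merged bottom-up by pair
# frequency (BPE-style) to a target size, plus begin/end tags.  The full-size
# vocabulary is 112 = 2 tags + 110 sub-tokens; an internal pad id (0) lives
# outside the one-hot/logit space.

BOS_TOKEN <- "<bos>"
EOS_TOKEN <- "<eos>"

# Split a SMILES string into syntactic base units: bracket atoms, %nn ring
# closures, two-character organic-subset elements, then single characters.
smiles_base_units <- function(smiles) {
  pat <- "(\\[[^\\]]*\\]|%[0-9]{2}|Cl|Br|.)"
  m <- gregexpr(pat, smiles, perl = TRUE)[[1]]
  if (m[1] == -1) return(character(0))
  regmatches(smiles, gregexpr(pat, smiles, perl = TRUE))[[1]]
}

#' Build a sub-token SMILES vocabulary
#'
#' Starts from the corpus's syntactic base units and iteratively merges the
#' most frequent adjacent pair (ties broken lexicographically by the merged
#' string) until `target_size` sub-tokens exist.  Begin/end tags occupy the
#' first two ids; the internal pad id is 0 and is outside the one-hot space.
#'
#' @param corpus_smiles character vector of SMILES strings.
#' @param target_size sub-token count to aim for (110 gives the full
#'   112-token vocabulary with tags).
#' @return a `Vocabulary`: list(tokens, bos_id = 1, eos_id = 2, pad_id = 0,
#'   size).
#' @export
build_vocabulary <- function(corpus_smiles, target_size = 110L) {
  stopifnot(length(corpus_smiles) >= 1L)
  seqs <- lapply(corpus_smiles, smiles_base_units)
  subtok <- sort(unique(unlist(seqs)))
  while (length(subtok) < target_size) {
    pairs <- unlist(lapply(seqs, function(s) {
      if (length(s) < 2L) return(character(0))
      paste(s[-length(s)], s[-1L], sep = "\x1f")
    }))
    if (length(pairs) == 0L) {
      warning(sprintf(
        "build_vocabulary: corpus exhausted at %d sub-tokens (target %d)",
        length(subtok), target_size))
      break
    }
    tab <- table(pairs)
    merged <- gsub("\x1f", "", names(tab), fixed = TRUE)
    best <- order(-as.integer(tab), merged)[1L]
    pair <- strsplit(names(tab)[best], "\x1f", fixed = TRUE)[[1]]
    new_tok <- merged[best]
    seqs <- lapply(seqs, merge_pair, left = pair[1], right = pair[2],
                   merged = new_tok)
    if (!new_tok %in% subtok) subtok <- c(subtok, new_tok)
  }
  tokens <- c(BOS_TOKEN, EOS_TOKEN, subtok)
  structure(list(tokens = tokens, bos_id = 1L, eos_id = 2L, pad_id = 0L,
                 size = length(tokens)),
            class = "Vocabulary")
}

merge_pair <- function(s, left, right, merged) {
  n <- length(s)
  if (n < 2L) return(s)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    if (i < n && s[i] == left && s[i + 1L] == right) {
      out <- c(out, merged)
      i <- i + 2L
    } else {
      out <- c(out, s[i])
      i <- i + 1L
    }
  }
  out
}

#' Tokenize a SMILES string / reassemble from ids
#'
#' `tokenize` applies greedy longest-match left-to-right over the sub-token
#' set and errors (naming the character offset) on uncoverable input.
#' `detokenize` concatenates sub-token strings, silently stripping tags and
#' padding.
#'
#' @param smiles SMILES string.
#' @param vocab a [build_vocabulary()] result.
#' @return integer vector of token ids (no tags).
#' @export
tokenize <- function(smiles, vocab) {
  subs <- vocab$tokens[-c(vocab$bos_id, vocab$eos_id)]
  if (length(subs) == 0L) stop("tokenize: empty vocabulary")
  lens <- sort(unique(nchar(subs)), decreasing = TRUE)
  lookup <- new.env(parent = emptyenv())
  for (i in seq_along(vocab$tokens))
    assign(vocab$tokens[i], i, envir = lookup)
  ids <- integer(0)
  i <- 1L
  nc <- nchar(smiles)
  while (i <= nc) {
    hit <- 0L
    for (L in lens) {
      if (i + L - 1L > nc) next
      cand <- substr(smiles, i, i + L - 1L)
      id <- lookup[[cand]]
      if (!is.null(id) && id > 2L) { hit <- id; i <- i + L; break }
    }
    if (hit == 0L)
      stop(sprintf("tokenize: no vocabulary token covers offset %d of '%s'",
                   i, smiles))
    ids <- c(ids, hit)
  }
  ids
}

#' @rdname tokenize
#' @param ids integer token ids (tags/pad allowed; stripped).
#' @export
detokenize <- function(ids, vocab) {
  keep <- ids > 2L & ids <= vocab$size
  paste(vocab$tokens[ids[keep]], collapse = "")
}

#' Vocabulary text serialization (one token per line, tags first)
#' @param vocab a `Vocabulary`.
#' @param path file path.
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(vocab$tokens, path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  tokens <- readLines(path)
  stopifnot(tokens[1] == BOS_TOKEN, tokens[2] == EOS_TOKEN)
  structure(list(tokens = tokens, bos_id = 1L, eos_id = 2L, pad_id = 0L,
                 size = length(tokens)),
            class = "Vocabulary")
}
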