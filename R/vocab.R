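# Character-level SMILES tokenization with two-character element symbols
# (Cl, Br, Si, Se) kept as single tokens, so the decoder can never emit the
# meaningless halves of a split element symbol.

.two_char_tokens <- c("Cl", "Br", "Si", "Se")
.special_tokens <- c("<pad>", "<s>", "</s>")

#' Split a SMILES string into tokens
#'
#' @param smiles a single SMILES string.
#' @return character vector of tokens.
#' @export
smiles_tokens <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    if (i < n) {
      pair <- paste0(chars[i], chars[i + 1L])
      if (pair %in% .two_char_tokens) {
        out <- c(out, pair)
        i <- i + 2L
        next
      }
    }
    out <- c(out, chars[i])
    i <- i + 1L
  }
  out
}

#' Build a token vocabulary from a curated corpus
#'
#' Specials (`<pad>`, `<s>`, `</s>`) come first, then all distinct corpus
#' tokens in sorted order, so the same corpus always yields the same
#' vocabulary.
#'
#' @param smiles character vector of curated canonical SMILES.
#' @return object of class `token_vocab`: list with `tokens`, `pad_id`,
#'   `start_id`, `end_id`, `size` and an index lookup.
#' @export
build_vocabulary <- function(smiles) {
  stopifnot(is.character(smiles))
  smiles <- smiles[!is.na(smiles)]
  if (length(smiles) == 0L) stop("cannot build a vocabulary from an empty corpus")
  toks <- sort(unique(unlist(lapply(smiles, smiles_tokens))), method = "radix")
  tokens <- c(.special_tokens, toks)
  structure(list(
    tokens = tokens,
    pad_id = 1L, start_id = 2L, end_id = 3L,
    size = length(tokens),
    index = stats::setNames(seq_along(tokens), tokens)
  ), class = "token_vocab")
}

#' @export
print.token_vocab <- function(x, ...) {
  cat(sprintf("<token vocabulary: %d tokens (3 special)>\n", x$size))
  cat(" ", paste(x$tokens[-(1:3)], collapse = " "), "\n")
  invisible(x)
}

#' Encode a SMILES string as a fixed-length id sequence
#'
#' The sequence is framed as `<s> tokens </s>` and padded with `<pad>` to
#' exactly `max_len` ids, so the maximum content length is `max_len - 2`.
#'
#' @param smiles a single SMILES string.
#' @param vocab a `token_vocab`.
#' @param max_len total encoded length (default 100).
#' @return integer vector of length `max_len`.
#' @export
tokenize <- function(smiles, vocab, max_len = 100L) {
  stopifnot(inherits(vocab, "token_vocab"))
  toks <- smiles_tokens(smiles)
  ids <- vocab$index[toks]
  if (anyNA(ids)) {
    bad <- unique(toks[is.na(ids)])
    stop(sprintf("token(s) not in vocabulary: %s", paste(bad, collapse = " ")))
  }
  if (length(ids) > max_len - 2L) {
    stop(sprintf("SMILES of %d tokens exceeds the %d-token content budget",
                 length(ids), max_len - 2L))
  }
  out <- c(vocab$start_id, unname(ids), vocab$end_id,
           rep(vocab$pad_id, max_len - length(ids) - 2L))
  as.integer(out)
}

#' Decode an id sequence back to a SMILES string
#'
#' Inverse of [tokenize()]: strips the start token, reads up to the first
#' end or pad token.
#'
#' @param ids integer vector of token ids.
#' @param vocab a `token_vocab`.
#' @return character SMILES string (possibly empty).
#' @export
detokenize <- function(ids, vocab) {
  stopifnot(inherits(vocab, "token_vocab"))
  if (any(ids < 1L | ids > vocab$size)) stop("token id out of range")
  if (length(ids) > 0L && ids[1] == vocab$start_id) ids <- ids[-1]
  stop_at <- which(ids == vocab$end_id | ids == vocab$pad_id)
  if (length(stop_at) > 0L) ids <- ids[seq_len(stop_at[1] - 1L)]
  ids <- ids[ids != vocab$start_id]
  paste(vocab$tokens[ids], collapse = "")
}

# Encode a whole corpus into an n x max_len integer matrix.
encode_corpus <- function(smiles, vocab, max_len = 100L) {
  t(vapply(smiles, tokenize, integer(max_len),
           vocab = vocab, max_len = max_len, USE.NAMES = FALSE))
}
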