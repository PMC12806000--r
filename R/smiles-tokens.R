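# Character-level SMILES tokenization for the purely convolutional
# two-branch model, which consumes drugs as token sequences rather than
# graphs.  The vocabulary is the set of distinct characters of the
# training corpus, frozen at fit time and persisted with checkpoints.

#' Build a character vocabulary from a SMILES corpus
#'
#' @param smiles Character vector of SMILES strings.
#' @return Object of class `smiles_vocabulary`: `symbols` (sorted distinct
#'   characters, indices `1..V`) and `size`; index 0 is the pad token.
#' @export
smiles_vocabulary <- function(smiles) {
  chars <- sort(unique(unlist(strsplit(smiles, ""))))
  if (length(chars) == 0) stop_invalid("empty SMILES corpus")
  structure(
    list(symbols = chars, size = length(chars)),
    class = "smiles_vocabulary"
  )
}

#' Encode a SMILES string as fixed-length integer tokens
#'
#' Characters are mapped to their vocabulary index; unknown characters map
#' to 0 (pad).  Truncates to the first `L` characters and pads with
#' trailing zeros.
#'
#' @param smiles A single SMILES string.
#' @param vocab A [smiles_vocabulary()].
#' @param L Fixed token length (default 100).
#' @return Integer vector of length `L`.
#' @export
encode_smiles <- function(smiles, vocab, L = 100L) {
  chars <- strsplit(smiles, "")[[1]]
  idx <- match(chars, vocab$symbols)
  idx[is.na(idx)] <- 0L
  tokens <- integer(L)
  keep <- seq_len(min(length(idx), L))
  tokens[keep] <- idx[keep]
  tokens
}

#' Encode a SMILES corpus as a token matrix
#'
#' @param smiles Character vector.
#' @inheritParams encode_smiles
#' @return Integer matrix, one row per string.
#' @export
encode_smiles_matrix <- function(smiles, vocab, L = 100L) {
  t(vapply(smiles, encode_smiles, integer(L), vocab = vocab, L = L))
}
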