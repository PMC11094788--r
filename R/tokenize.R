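# SMILES tokenization with the de-facto reaction-transformer token grammar:
# bracket atoms, two-letter organic-subset halogens, %nn ring closures and
# the ">" reaction separator are single tokens; everything else is one
# character. The only contract is the lossless round trip.

.smiles_token_rx <- paste0(
  "\\[[^\\]]*\\]",     # bracket atom, any content
  "|Br|Cl",            # two-letter organic-subset atoms
  "|%[0-9]{2}",        # two-digit ring closure
  "|>",                # reaction separator
  "|[BCNOPSFIbcnops]", # organic-subset atoms
  "|[0-9]",            # ring bonds
  "|[().=#+:/\\\\~*$-]", # bonds, branches, dot, charge-ish leftovers
  "|@@|@"              # tetrahedral marks
)

#' Tokenize a SMILES or reaction-SMILES string
#'
#' Splits a SMILES string into model-ready tokens: bracket atoms (e.g.
#' `[OH:2]`, `[nH]`), `Cl`/`Br`, two-digit `%nn` ring closures and `>` are
#' single tokens; all remaining characters are one token each. Tokenization
#' is lossless: `paste(tokens, collapse = "")` reproduces the input exactly.
#'
#' @param smiles A single SMILES (or `left>middle>right` reaction) string.
#' @return Character vector of tokens.
#' @seealso [detokenize_smiles()]
#' @export
tokenize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  m <- gregexpr(.smiles_token_rx, smiles, perl = TRUE)[[1]]
  tokens <- regmatches(smiles, list(m))[[1]]
  # verify contiguous coverage; report first untokenizable position
  pos <- 1L
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  if (length(starts) == 1L && starts[1] == -1L) {
    starts <- integer(0); lens <- integer(0)
  }
  for (i in seq_along(starts)) {
    if (starts[i] != pos) {
      abort(sprintf("untokenizable character '%s' at position %d in \"%s\"",
                    substr(smiles, pos, pos), pos, smiles))
    }
    pos <- pos + lens[i]
  }
  if (pos != nchar(smiles) + 1L) {
    abort(sprintf("untokenizable character '%s' at position %d in \"%s\"",
                  substr(smiles, pos, pos), pos, smiles))
  }
  tokens
}

#' Reassemble a token vector into a SMILES string
#'
#' Inverse of [tokenize_smiles()].
#'
#' @param tokens Character vector of tokens.
#' @return Single string.
#' @export
detokenize_smiles <- function(tokens) {
  paste(tokens, collapse = "")
}

# atom-bearing tokens (used to count atoms when choosing a random
# rewrite start atom)
is_atom_token <- function(tokens) {
  grepl("^\\[", tokens) | tokens %in%
    c("Br", "Cl", "B", "C", "N", "O", "P", "S", "F", "I",
      "b", "c", "n", "o", "p", "s")
}
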