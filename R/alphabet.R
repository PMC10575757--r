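#' The 20 canonical amino acids
#'
#' One-letter codes in the fixed order used throughout the package (token
#' ids 1--20 in the generative model, column order of positional matrices).
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Generative-model vocabulary
#'
#' The 20 amino acids plus start, end and pad control tokens (23 tokens).
#'
#' @return Named integer vector mapping token string to token id.
#' @export
model_vocabulary <- function() {
  toks <- c(amino_acids(), "<start>", "<end>", "<pad>")
  setNames(seq_along(toks), toks)
}

# validate amino-acid strings; empty strings pass when allow_empty
check_aa <- function(x, what = "sequence", allow_empty = TRUE) {
  x <- as.character(x)
  if (anyNA(x)) abort(sprintf("%s contains NA", what))
  bad <- !grepl(sprintf("^[%s]*$", paste(amino_acids(), collapse = "")), x)
  if (any(bad)) {
    i <- which(bad)[1]
    chars <- strsplit(x[i], "")[[1]]
    off <- setdiff(chars, amino_acids())[1]
    abort(sprintf(
      "invalid %s '%s': character '%s' is not a canonical amino acid",
      what, x[i], off))
  }
  if (!allow_empty && any(!nzchar(x))) {
    abort(sprintf("%s must be non-empty", what))
  }
  invisible(x)
}

# tokenise CDR triplets: <start> + concatenated residues + <end>
triplet_tokens <- function(cdr1, cdr2, cdr3) {
  vocab <- model_vocabulary()
  seqs <- paste0(cdr1, cdr2, cdr3)
  lapply(seqs, function(s) {
    res <- if (nzchar(s)) vocab[strsplit(s, "")[[1]]] else integer(0)
    unname(c(vocab["<start>"], res, vocab["<end>"]))
  })
}
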