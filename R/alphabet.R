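#' The amino-acid alphabet used for one-hot encoding
#'
#' The 20 standard amino acids in fixed alphabetical order of their one-letter
#' codes. This ordering defines the channel layout of every encoded tensor in
#' the package and is identical across all encode/decode calls; channel `i` of
#' a peptide tensor is residue `aa_alphabet()[i]`. The gap symbol `"-"` is not
#' part of the residue alphabet — aligned HLA tensors carry it on a dedicated
#' 21st channel.
#'
#' @return Character vector of length 20.
#' @examples
#' aa_alphabet()
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname aa_alphabet
#' @export
gap_symbol <- function() "-"

# channel index (1..20) of each residue character; NA for anything else
aa_channel <- function(chars) {
  match(chars, aa_alphabet())
}

# width of the fixed HLA alignment window
HLA_WIDTH <- 372L
# gap channel index in the HLA tensor
GAP_CHANNEL <- 21L
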