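#' One-hot encode a 9-mer peptide
#'
#' Encodes a 9-residue peptide string as a binary tensor of shape
#' 1 (height) x 9 (width) x 20 (channel). Column `j` carries a single 1 at
#' the channel of residue `j` (channels ordered as [aa_alphabet()]); no
#' physicochemical information is encoded. Lower-case input is upper-cased
#' before validation.
#'
#' @param seq A single 9-character string over the 20 standard amino acids.
#' @return A numeric array with `dim = c(1, 9, 20)` whose columns each sum
#'   to 1 (exactly 9 ones in total).
#' @seealso [decode_peptide()], [encode_hla()]
#' @examples
#' t <- encode_peptide("HLNPNKTKR")
#' dim(t)
#' decode_peptide(t)
#' @export
encode_peptide <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(chars) != 9L) {
    abort(sprintf("peptide must have length 9, got %d (\"%s\")", length(chars), seq),
          class = "panbinder_length_error")
  }
  ch <- aa_channel(chars)
  if (anyNA(ch)) {
    bad <- unique(chars[is.na(ch)])
    abort(sprintf("peptide contains non-standard characters: %s",
                  paste(bad, collapse = ", ")),
          class = "panbinder_alphabet_error")
  }
  out <- array(0, dim = c(1L, 9L, 20L))
  out[cbind(1L, seq_len(9L), ch)] <- 1
  out
}

#' One-hot encode an aligned HLA protein sequence
#'
#' Encodes an alignment-ready HLA sequence (residues and `-` gaps, length at
#' most 372) as a binary tensor of shape 1 x 372 x 21. Channels 1..20 are the
#' residue channels of [aa_alphabet()]; channel 21 is the gap channel, which
#' also absorbs the right-padding columns used to bring shorter sequences up
#' to the fixed width of 372. Every column sums to exactly 1.
#'
#' @param aligned_seq A single string of residues and `-`, length <= 372.
#' @return A numeric array with `dim = c(1, 372, 21)`.
#' @examples
#' h <- encode_hla(strrep("A", 370))
#' sum(h[1, , 21])  # two right-padding columns on the gap channel
#' @export
encode_hla <- function(aligned_seq) {
  stopifnot(is.character(aligned_seq), length(aligned_seq) == 1L, !is.na(aligned_seq))
  aligned_seq <- toupper(aligned_seq)
  chars <- strsplit(aligned_seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n > HLA_WIDTH) {
    abort(sprintf("aligned HLA sequence longer than %d (got %d)", HLA_WIDTH, n),
          class = "panbinder_length_error")
  }
  ch <- aa_channel(chars)
  ch[chars == gap_symbol()] <- GAP_CHANNEL
  if (anyNA(ch)) {
    bad <- unique(chars[is.na(ch)])
    abort(sprintf("HLA sequence contains illegal characters: %s",
                  paste(bad, collapse = ", ")),
          class = "panbinder_alphabet_error")
  }
  out <- array(0, dim = c(1L, HLA_WIDTH, GAP_CHANNEL))
  if (n > 0L) out[cbind(1L, seq_len(n), ch)] <- 1
  if (n < HLA_WIDTH) out[1L, (n + 1L):HLA_WIDTH, GAP_CHANNEL] <- 1
  out
}

#' Decode a one-hot peptide tensor back to its sequence
#'
#' Inverse of [encode_peptide()]: `decode_peptide(encode_peptide(s))` equals
#' `s` for every valid 9-mer.
#'
#' @param tensor A 1 x 9 x 20 array in which every column has exactly one hot
#'   channel.
#' @return The 9-character peptide string.
#' @export
decode_peptide <- function(tensor) {
  if (!is.array(tensor) || !identical(dim(tensor), c(1L, 9L, 20L))) {
    abort("expected a 1 x 9 x 20 peptide tensor", class = "panbinder_malformed_tensor")
  }
  m <- matrix(tensor[1L, , ], nrow = 9L)
  hot <- apply(m, 1L, function(col) which(col == 1))
  if (!is.integer(hot) || length(hot) != 9L || any(rowSums(m) != 1)) {
    abort("malformed peptide tensor: each column must have exactly one hot channel",
          class = "panbinder_malformed_tensor")
  }
  paste(aa_alphabet()[hot], collapse = "")
}

#' Read aligned HLA sequences from FASTA
#'
#' Reads a FASTA file of alignment-ready HLA protein sequences. The record id
#' (first whitespace-delimited token of the header) is taken as the allele
#' name, e.g. `HLA-A*02:01`. `-` is the only gap character accepted; sequences
#' must be at most 372 columns wide. Each sequence is validated by encoding it
#' once.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector mapping allele name to aligned sequence
#'   (the allele index used throughout the package).
#' @export
read_allele_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(names(seqs))) {
    abort("duplicate allele ids in FASTA", class = "panbinder_format_error")
  }
  for (s in seqs) encode_hla(s)  # validates width and alphabet
  seqs
}

#' Write an allele index to FASTA
#'
#' @param alleles Named character vector of aligned sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allele_fasta <- function(alleles, path) {
  set <- Biostrings::BStringSet(alleles)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
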