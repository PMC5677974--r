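# CpG dinucleotide counting on reference sequences.

#' Count CpG dinucleotides in reference sequences
#'
#' Counts occurrences of the CG dinucleotide on the forward strand of each
#' sequence (one count per CpG unit: the reverse-strand CG of the same
#' dinucleotide is not counted again). Applied to the autosomes of a
#' reference genome this gives the number of autosomal CpG sites.
#'
#' @param x A [Biostrings::DNAStringSet], a single character string of
#'   sequence, or a path to a FASTA file.
#' @param autosomes_only Restrict to sequences named like autosomes
#'   (`chr1`-`chr22` or `1`-`22`); default `FALSE`.
#' @return List with `total` and per-sequence counts `per_seq`.
#' @export
count_cpg_sites <- function(x, autosomes_only = FALSE) {
  seqs <- if (is(x, "DNAStringSet")) x
  else if (is.character(x) && length(x) == 1L && file.exists(x))
    Biostrings::readDNAStringSet(x)
  else Biostrings::DNAStringSet(x)
  if (autosomes_only) {
    nm <- sub("\\s.*$", "", names(seqs) %||% "")
    seqs <- seqs[is_autosome(nm)]
  }
  counts <- Biostrings::vcountPattern("CG", seqs)
  names(counts) <- sub("\\s.*$", "", names(seqs) %||% as.character(seq_along(seqs)))
  list(total = sum(counts), per_seq = counts)
}
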