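# small, fast designs used across test files

small_design <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 80, gene_length_range = c(100L, 400L),
         library_depth = 8000, seed = 11),
    list(...))
  do.call(synthetic_design, args)
}

# zero-noise variant: no errors, no adaptor/N reads, every gene taggable
noiseless_design <- function(...) {
  small_design(error_rate = 0, adaptor_only_rate = 0, n_read_rate = 0,
               catg_fraction = 1, ...)
}

# Hamming distance between equal-length strings
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# reverse complement of a plain character string
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# build a reference index directly from named tag-bearing sequences
seqs_with_tags <- function(...) {
  x <- c(...)
  Biostrings::DNAStringSet(x)
}

# expression matrix from plain matrices, for constructed DE cases
toy_expr <- function(counts, totals = NULL, lengths = NULL) {
  if (is.null(totals))
    totals <- setNames(rep(1e6, ncol(counts)), colnames(counts))
  if (is.null(lengths))
    lengths <- setNames(rep(1000L, nrow(counts)), rownames(counts))
  expression_matrix(counts, lib_totals = totals, gene_lengths = lengths)
}
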