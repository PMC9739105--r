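#' Pairwise percent identity by global alignment
#'
#' Needleman-Wunsch global alignment with match = 1, mismatch = 0 and a
#' linear gap penalty of -1 per gapped position; percent identity is the
#' number of identical aligned columns divided by the alignment length
#' (gapped columns included). This is the convention under which the 45-mer
#' and its 1-43 truncation score 95.6%.
#'
#' @param seq_a,seq_b Non-empty amino-acid sequences (strings).
#' @return Percent identity in `[0, 100]`.
#' @examples
#' mtx <- myotoxin3_peptide("45H")$sequence
#' pairwise_identity(mtx, substr(mtx, 1, 43))  # 95.6
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  for (s in list(seq_a, seq_b))
    if (!is.character(s) || length(s) != 1L || nchar(s) == 0L)
      stop("sequences must be non-empty strings")
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  letters <- unique(strsplit(paste0(seq_a, seq_b), "", fixed = TRUE)[[1L]])
  sub <- matrix(0, length(letters), length(letters),
                dimnames = list(letters, letters))
  diag(sub) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = sub, gapOpening = 0, gapExtension = 1,
    type = "global"
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  ident <- sum(p == s & p != "-")
  100 * ident / length(p)
}
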