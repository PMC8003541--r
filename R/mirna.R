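#' Mature miR-29 family sequences
#'
#' Packaged mature sequences of the three human miR-29 family members
#' (miRBase v22). All three share the seed (positions 2-8), so canonical
#' target sites are identical across the family; miR-29a-3p and miR-29c-3p
#' differ at a single nucleotide outside the seed, which is why mature-miRNA
#' qPCR assays cannot distinguish them.
#'
#' @return A named [Biostrings::RNAStringSet] with the three mature
#'   sequences, 5' to 3'.
#' @examples
#' fam <- mir29Family()
#' seedSequence(fam[["hsa-miR-29a-3p"]])
#' @export
mir29Family <- function() {
  Biostrings::RNAStringSet(c(
    "hsa-miR-29a-3p" = "UAGCACCAUCUGAAAUCGGUUA",
    "hsa-miR-29b-3p" = "UAGCACCAUUUGAAAUCAGUGUU",
    "hsa-miR-29c-3p" = "UAGCACCAUUUGAAAUCGGUUA"
  ))
}

#' Extract the seed sequence of a mature miRNA
#'
#' The seed is the 7-nt substring at positions 2-8 (1-based, inclusive) of
#' the mature sequence; Watson-Crick complementarity of a 3'UTR stretch to
#' the seed defines canonical target sites.
#'
#' @param mirna A mature miRNA sequence: a single character string, an
#'   [Biostrings::RNAString], or an [Biostrings::RNAStringSet] (seeds are
#'   returned per element).
#' @return Character vector of 7-nt seed sequences (RNA alphabet).
#' @export
seedSequence <- function(mirna) {
  s <- toupper(as.character(mirna))
  if (any(nchar(s) < 8L))
    stop("mature miRNA sequence must be at least 8 nt to carry a seed")
  substr(s, 2L, 8L)
}

.COMP_RNA <- c(A = "U", C = "G", G = "C", U = "A", T = "A", N = "N")
.COMP_DNA <- c(A = "T", C = "G", G = "C", U = "A", T = "A", N = "N")

#' Reverse complement of a nucleotide string
#'
#' Watson-Crick reverse complement with T and U treated as equivalent.
#' The output alphabet follows the input: a sequence containing U (and no T)
#' is complemented in RNA, anything else in DNA. An empty string returns an
#' empty string.
#'
#' @param x Character vector of sequences over the alphabet A, C, G, T, U, N
#'   (case-insensitive).
#' @param as Output alphabet: `"auto"` (default, follow the input), `"RNA"`
#'   or `"DNA"`.
#' @return Character vector of reverse complements.
#' @examples
#' revComp("AGCACCA", as = "RNA")  # "UGGUGCU"
#' @export
revComp <- function(x, as = c("auto", "RNA", "DNA")) {
  as <- match.arg(as)
  vapply(as.character(x), function(s) {
    su <- toupper(s)
    if (nchar(su) == 0L) return("")
    chars <- strsplit(su, "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% names(.COMP_RNA))
    if (length(bad))
      stop(sprintf("invalid nucleotide '%s' at position %d", chars[bad[1L]], bad[1L]))
    rna <- switch(as,
      auto = any(chars == "U") && !any(chars == "T"),
      RNA = TRUE, DNA = FALSE)
    comp <- if (rna) .COMP_RNA else .COMP_DNA
    paste(rev(unname(comp[chars])), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# normalize any sequence input to an uppercase RNA character vector (T -> U)
.asRnaChar <- function(x) {
  s <- toupper(as.character(x))
  chartr("T", "U", s)
}
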