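#' Scan 3'UTR sequences for canonical miR-29 seed-match sites
#'
#' Detects and classifies canonical seed-match sites on the sense strand of
#' 3'UTR sequences. The 6-nt core is the reverse complement of miRNA
#' positions 2-7. A core occurrence is upgraded to \code{7mer-m8} when the
#' UTR base immediately 5' of the core pairs with miRNA position 8, to
#' \code{7mer-A1} when the base immediately 3' of the core is an A
#' (opposite miRNA position 1), and to \code{8mer} when both hold. Each core
#' occurrence is reported once, at its maximal type, with coordinates
#' spanning the full site.
#'
#' @param mirna Mature miRNA sequence (character, [Biostrings::RNAString],
#'   or a length-1 [Biostrings::RNAStringSet]); at least 8 nt so the seed
#'   (positions 2-8) is defined.
#' @param utrs Named character vector, [Biostrings::DNAStringSet] or
#'   [Biostrings::RNAStringSet] of 3'UTR sequences (sense strand; T and U
#'   are equivalent).
#' @return A [GenomicRanges::GRanges] with one range per site:
#'   \code{seqnames} = gene identifier, 1-based closed coordinates over the
#'   full site (use [exportSitesBed()] for the 0-based half-open BED view),
#'   and metadata columns \code{site_type} (factor with levels
#'   \code{8mer > 7mer-m8 > 7mer-A1 > 6mer}) and \code{site_seq}.
#' @examples
#' sites <- findSeedSites(mir29Family()[1], c(geneA = "AAUGGUGCUAAA"))
#' sites  # one 8mer, BED start 2 (0-based), end 10
#' @export
findSeedSites <- function(mirna, utrs) {
  if (is(mirna, "XStringSet")) {
    if (length(mirna) != 1L)
      stop("'mirna' must be a single mature sequence")
    mirna <- as.character(mirna)
  }
  seed <- seedSequence(mirna)       # errors if < 8 nt
  useq <- .asRnaChar(utrs)
  ids <- names(utrs)
  if (is.null(ids)) ids <- names(useq)
  if (is.null(ids))
    stop("'utrs' must be named by gene identifier")
  names(useq) <- ids

  core6 <- revComp(substr(seed, 1L, 6L), as = "RNA")   # rc of miRNA pos 2-7
  m8c <- unname(.COMP_RNA[substr(seed, 7L, 7L)])       # pairs miRNA pos 8

  hits <- Biostrings::vmatchPattern(core6, Biostrings::RNAStringSet(useq))
  res <- lapply(seq_along(useq), function(i) {
    st <- BiocGenerics::start(hits[[i]])               # 1-based core start
    if (!length(st)) return(NULL)
    s <- useq[[i]]
    len <- nchar(s)
    five <- ifelse(st > 1L, substr(rep(s, length(st)), st - 1L, st - 1L), "")
    three <- ifelse(st + 6L <= len, substr(rep(s, length(st)), st + 6L, st + 6L), "")
    hasM8 <- five == m8c
    hasA1 <- three == "A"
    type <- ifelse(hasM8 & hasA1, "8mer",
            ifelse(hasM8, "7mer-m8",
            ifelse(hasA1, "7mer-A1", "6mer")))
    from <- ifelse(hasM8, st - 1L, st)
    to <- ifelse(hasA1, st + 6L, st + 5L)
    data.frame(gene_id = ids[i], start = from, end = to,
               site_type = type,
               site_seq = substr(rep(s, length(st)), from, to))
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$site_type <- factor(character(0),
      levels = c("8mer", "7mer-m8", "7mer-A1", "6mer"))
    S4Vectors::mcols(gr)$site_seq <- character(0)
    return(gr)
  }
  GenomicRanges::GRanges(
    seqnames = res$gene_id,
    ranges = IRanges::IRanges(start = res$start, end = res$end),
    strand = "+",
    site_type = factor(res$site_type,
      levels = c("8mer", "7mer-m8", "7mer-A1", "6mer")),
    site_seq = res$site_seq)
}

#' Summarize seed sites per gene and merge external algorithm support
#'
#' Produces one row per gene present in either the site scan or the support
#' table: per-type site counts, the best site type present
#' (\code{8mer > 7mer-m8 > 7mer-A1 > 6mer}), the number of external
#' prediction algorithms supporting the gene, and its conservation flag.
#' Genes absent from the support table get \code{n_algorithms = 0} and
#' \code{conserved = FALSE}; genes with support but no detected site keep
#' zero site counts.
#'
#' @param sites A [GenomicRanges::GRanges] from [findSeedSites()].
#' @param support A data.frame with columns \code{gene_id},
#'   \code{n_algorithms} and \code{conserved} (0/1 or logical); one row per
#'   gene. May be `NULL` or empty.
#' @return A data.frame with columns \code{gene_id}, \code{n_8mer},
#'   \code{n_7mer_m8}, \code{n_7mer_A1}, \code{n_6mer}, \code{n_sites},
#'   \code{best_type}, \code{n_algorithms}, \code{conserved}.
#' @export
summarizeGeneSites <- function(sites, support = NULL) {
  lev <- c("8mer", "7mer-m8", "7mer-A1", "6mer")
  if (length(sites)) {
    tab <- table(as.character(GenomicRanges::seqnames(sites)),
                 factor(S4Vectors::mcols(sites)$site_type, levels = lev))
    cnt <- as.data.frame.matrix(tab)
    cnt$gene_id <- rownames(cnt)
  } else {
    cnt <- data.frame(matrix(integer(0), ncol = 4,
                             dimnames = list(NULL, lev)), check.names = FALSE)
    cnt$gene_id <- character(0)
  }
  if (!is.null(support) && nrow(support)) {
    req <- c("gene_id", "n_algorithms", "conserved")
    if (!all(req %in% names(support)))
      stop("support table needs columns gene_id, n_algorithms, conserved")
    if (anyDuplicated(support$gene_id))
      stop("duplicate gene rows in support table")
  } else {
    support <- data.frame(gene_id = character(0), n_algorithms = integer(0),
                          conserved = logical(0))
  }
  genes <- union(cnt$gene_id, support$gene_id)
  if (!length(genes)) {
    return(data.frame(gene_id = character(0), n_8mer = integer(0),
      n_7mer_m8 = integer(0), n_7mer_A1 = integer(0), n_6mer = integer(0),
      n_sites = integer(0),
      best_type = factor(character(0), levels = c(lev, "none")),
      n_algorithms = integer(0), conserved = logical(0)))
  }
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  idx <- match(genes, cnt$gene_id)
  for (k in seq_along(lev)) {
    v <- ifelse(is.na(idx), 0L, as.integer(cnt[[lev[k]]][idx]))
    out[[c("n_8mer", "n_7mer_m8", "n_7mer_A1", "n_6mer")[k]]] <- v
  }
  m <- as.matrix(out[, c("n_8mer", "n_7mer_m8", "n_7mer_A1", "n_6mer")])
  out$n_sites <- as.integer(rowSums(m))
  best <- apply(m, 1L, function(r) if (any(r > 0)) lev[which(r > 0)[1L]] else "none")
  out$best_type <- factor(best, levels = c(lev, "none"))
  sidx <- match(genes, support$gene_id)
  out$n_algorithms <- ifelse(is.na(sidx), 0L,
                             as.integer(support$n_algorithms[sidx]))
  out$conserved <- ifelse(is.na(sidx), FALSE,
                          as.logical(support$conserved[sidx]))
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Write seed sites as BED6
#'
#' Exports the site ranges in BED6 convention: 0-based half-open
#' coordinates, \code{chrom} = gene identifier, \code{name} = site type,
#' \code{score} = 0, \code{strand} = "+".
#'
#' @param sites A [GenomicRanges::GRanges] from [findSeedSites()].
#' @param file Output path.
#' @return Invisibly, the path written.
#' @export
exportSitesBed <- function(sites, file) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(sites)),
    start = BiocGenerics::start(sites) - 1L,
    end = BiocGenerics::end(sites),
    name = as.character(S4Vectors::mcols(sites)$site_type),
    score = 0L,
    strand = "+")
  write.table(df, file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}
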