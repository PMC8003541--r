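#' Read and write pipeline tables
#'
#' Plain-text interchange used by the pipeline: a counts TSV (first column
#' \code{gene_id}, one column per sample), a two-column metadata TSV
#' (\code{sample_id}, \code{condition}), a support TSV (\code{gene_id},
#' \code{n_algorithms}, \code{conserved} 0/1), and a survival TSV
#' (\code{subject_id}, \code{time}, \code{event}, \code{group}).
#'
#' @param se SummarizedExperiment with a \code{"counts"} assay and
#'   \code{colData$condition}.
#' @param countsFile,metaFile,file Paths.
#' @return `writeCountExperiment` invisibly returns the paths written;
#'   `readCountExperiment` returns a SummarizedExperiment; the table
#'   readers/writers return/consume plain data.frames.
#' @name pipeline-io
NULL

#' @rdname pipeline-io
#' @export
writeCountExperiment <- function(se, countsFile, metaFile) {
  counts <- SummarizedExperiment::assay(se, "counts")
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, countsFile, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = colnames(counts),
                     condition = SummarizedExperiment::colData(se)$condition)
  write.table(meta, metaFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(countsFile, metaFile))
}

#' @rdname pipeline-io
#' @export
readCountExperiment <- function(countsFile, metaFile) {
  df <- read.delim(countsFile, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1L]]
  meta <- read.delim(metaFile)
  counts <- counts[, meta$sample_id, drop = FALSE]
  makeCountExperiment(counts, meta$condition)
}

#' @rdname pipeline-io
#' @param support,surv data.frames to write.
#' @export
writeSupportTsv <- function(support, file) {
  out <- support
  out$conserved <- as.integer(out$conserved)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname pipeline-io
#' @export
readSupportTsv <- function(file) {
  df <- read.delim(file)
  df$conserved <- as.logical(df$conserved)
  df
}

#' @rdname pipeline-io
#' @export
writeSurvivalTsv <- function(surv, file) {
  write.table(surv, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname pipeline-io
#' @export
readSurvivalTsv <- function(file) read.delim(file)
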