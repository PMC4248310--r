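# Plain-text readers/writers for the pipeline's interchange formats.

#' Write a numeric matrix as TSV with an id column
#' @param x Matrix with rownames.
#' @param path Output file.
#' @param id_col Name of the leading identifier column.
#' @export
write_tsv_matrix <- function(x, path, id_col = "gene_id") {
  df <- data.frame(rownames(x), as.data.frame(x), check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV matrix written by [write_tsv_matrix()]
#' @param path Input file.
#' @return Numeric matrix with rownames from the first column.
#' @export
read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write binned coverage as bedGraph (0-based half-open)
#' @param cov data.frame with columns chrom, start, end, score.
#' @param path Output file.
#' @export
write_bedgraph <- function(cov, path) {
  gr <- GenomicRanges::GRanges(cov$chrom,
                               IRanges::IRanges(cov$start + 1L, cov$end),
                               score = cov$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file into a coverage data.frame
#' @param path bedGraph file.
#' @return data.frame(chrom, start, end, score), 0-based half-open.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             score = gr$score)
}

#' Write a cells-by-genes matrix as MatrixMarket with row/column name files
#' @param m Numeric matrix (cells in rows).
#' @param prefix Path prefix; writes `<prefix>.mtx`, `<prefix>.rows.tsv`,
#'   `<prefix>.cols.tsv`.
#' @export
write_mtx <- function(m, prefix) {
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), paste0(prefix, ".mtx"))
  writeLines(rownames(m), paste0(prefix, ".rows.tsv"))
  writeLines(colnames(m), paste0(prefix, ".cols.tsv"))
  invisible(prefix)
}

#' Read a matrix written by [write_mtx()]
#' @param prefix Path prefix used at write time.
#' @return Dense numeric matrix with dimnames.
#' @export
read_mtx <- function(prefix) {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  rownames(m) <- readLines(paste0(prefix, ".rows.tsv"))
  colnames(m) <- readLines(paste0(prefix, ".cols.tsv"))
  m
}
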