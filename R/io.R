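# Plain-text readers/writers for count matrices and metadata.
# TSV layout: first column "gene", remaining columns one per sample.
# MatrixMarket layout: <stem>.mtx plus <stem>.rownames / <stem>.colnames.

#' Write a count matrix as TSV
#' @param counts gene x sample matrix with dimnames.
#' @param path output file.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix from TSV
#' @param path file written by [write_counts_tsv()] (or any TSV whose first
#'   column holds gene ids).
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix in MatrixMarket form
#' @param counts gene x sample matrix.
#' @param stem path stem; writes `<stem>.mtx`, `<stem>.rownames`,
#'   `<stem>.colnames`.
#' @export
write_counts_mtx <- function(counts, stem) {
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), paste0(stem, ".mtx"))
  writeLines(rownames(counts), paste0(stem, ".rownames"))
  writeLines(colnames(counts), paste0(stem, ".colnames"))
  invisible(stem)
}

#' Read a count matrix written by [write_counts_mtx()]
#' @param stem path stem.
#' @return integer matrix.
#' @export
read_counts_mtx <- function(stem) {
  m <- as.matrix(Matrix::readMM(paste0(stem, ".mtx")))
  rownames(m) <- readLines(paste0(stem, ".rownames"))
  colnames(m) <- readLines(paste0(stem, ".colnames"))
  storage.mode(m) <- "integer"
  m
}

#' Write/read the sample metadata table
#' @param metadata data frame with columns sample_id, source, group, subject.
#' @param path TSV file.
#' @export
write_metadata_tsv <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_tsv
#' @export
read_metadata_tsv <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "source", "group", "subject")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("metadata is missing required column(s): ", paste(miss, collapse = ", "))
  md
}

#' Write an R object as JSON
#' @param x object (lists/vectors/data frames).
#' @param path output file.
#' @export
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_json_file
#' @export
read_json_file <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
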