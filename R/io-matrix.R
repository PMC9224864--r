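#' Write a labelled matrix as tab-separated text
#'
#' Square similarity matrices, score matrices and latent-factor matrices
#' are all serialized the same way: a header row of column ids, then one
#' row per line starting with its row id.
#'
#' @param m numeric matrix with dimnames (at least colnames).
#' @param path output path.
#' @export
write_similarity_matrix <- function(m, path) {
  df <- as.data.frame(m)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Read a labelled tab-separated matrix
#'
#' Inverse of [write_similarity_matrix()].
#'
#' @param path input path.
#' @return numeric matrix with dimnames.
#' @export
read_similarity_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                          check.names = FALSE)
  as.matrix(df)
}
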