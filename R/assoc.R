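#' Construct a binary miRNA-disease association matrix
#'
#' The association matrix is the central data object: a p x q binary matrix
#' whose rows are miRNAs, columns are diseases, and entries are 1 where an
#' experimentally supported association is known and 0 otherwise. Row and
#' column order is always the lexicographic order of the ids so that the
#' same inputs yield the same index layout across runs.
#'
#' @param pairs two-column character matrix or data.frame of
#'   (miRNA id, disease id) pairs; duplicates collapse to a single 1.
#' @return a binary integer matrix with miRNA ids as rownames and disease
#'   ids as colnames.
#' @examples
#' association_matrix(cbind(c("m1", "m2", "m1"), c("d1", "d2", "d1")))
#' @export
association_matrix <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0L) stop("no associations")
  if (ncol(pairs) < 2L) stop("pairs must have at least two columns")
  mirna <- sort(unique(as.character(pairs[, 1L])))
  disease <- sort(unique(as.character(pairs[, 2L])))
  y <- matrix(0L, nrow = length(mirna), ncol = length(disease),
              dimnames = list(mirna, disease))
  y[cbind(as.character(pairs[, 1L]), as.character(pairs[, 2L]))] <- 1L
  y
}

#' Read a tab-separated miRNA-disease association list
#'
#' Each non-comment line holds one known association: miRNA id, tab,
#' disease id. Lines starting with '#' are ignored. Duplicate pairs are
#' collapsed; ids are deduplicated and sorted lexicographically so the
#' resulting index order is deterministic.
#'
#' @param path path to the pair-list file.
#' @return binary association matrix (see [association_matrix()]).
#' @export
read_association_pairs <- function(path) {
  lines <- read_clean_lines(path)
  if (length(lines) == 0L) stop("no associations in '", path, "'")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- which(nf < 2L)[1L]
    stop("malformed association row (expected 2 tab-separated fields) at line ",
         attr(lines, "line_numbers")[bad], " of '", path, "'")
  }
  pairs <- cbind(vapply(fields, `[[`, character(1L), 1L),
                 vapply(fields, `[[`, character(1L), 2L))
  association_matrix(pairs)
}

#' Write an association matrix back to a tab-separated pair list
#'
#' Inverse of [read_association_pairs()]: one line per known association,
#' in row-major order of the sorted ids, so that a round trip reproduces an
#' identical matrix.
#'
#' @param assoc binary association matrix with dimnames.
#' @param path output path.
#' @export
write_association_pairs <- function(assoc, path) {
  check_assoc(assoc)
  idx <- which(assoc == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  lines <- paste(rownames(assoc)[idx[, 1L]], colnames(assoc)[idx[, 2L]],
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# Reads lines, drops '#' comments and blanks, keeps original line numbers
# for error messages.
read_clean_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  out <- raw[keep]
  attr(out, "line_numbers") <- which(keep)
  out
}

check_assoc <- function(assoc) {
  stopifnot(is.matrix(assoc))
  if (is.null(rownames(assoc)) || is.null(colnames(assoc)))
    stop("association matrix must carry miRNA rownames and disease colnames")
  if (anyDuplicated(rownames(assoc)) || anyDuplicated(colnames(assoc)))
    stop("duplicate ids in association matrix dimnames")
  if (!all(assoc %in% c(0L, 1L)))
    stop("association matrix entries must be 0 or 1")
  invisible(assoc)
}
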