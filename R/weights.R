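#' Read a tab-separated miRNA expression table
#'
#' Two dialects are accepted. The two-column form (miRNA id, value) gives
#' one expression value per miRNA, later broadcast across all diseases.
#' The three-column form (miRNA id, condition/disease id, value) gives a
#' per-(miRNA, condition) value. Lines starting with '#' are ignored.
#'
#' @param path path to the expression file.
#' @return data.frame with columns `mirna`, `condition` (NA for the
#'   two-column dialect) and `value`.
#' @export
read_expression_table <- function(path) {
  lines <- read_clean_lines(path)
  if (length(lines) == 0L) stop("empty expression table '", path, "'")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (!all(nf %in% c(2L, 3L)) || length(unique(nf)) != 1L) {
    bad <- which(!nf %in% c(2L, 3L))
    at <- if (length(bad)) attr(lines, "line_numbers")[bad[1L]] else
      attr(lines, "line_numbers")[1L]
    stop("expression rows must all have 2 or 3 tab-separated fields ",
         "(problem near line ", at, " of '", path, "')")
  }
  if (nf[1L] == 2L) {
    out <- data.frame(
      mirna = vapply(fields, `[[`, character(1L), 1L),
      condition = NA_character_,
      value = as.numeric(vapply(fields, `[[`, character(1L), 2L)),
      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(
      mirna = vapply(fields, `[[`, character(1L), 1L),
      condition = vapply(fields, `[[`, character(1L), 2L),
      value = as.numeric(vapply(fields, `[[`, character(1L), 3L)),
      stringsAsFactors = FALSE)
  }
  if (any(!is.finite(out$value)))
    stop("non-finite expression value in '", path, "'")
  out
}

#' Build the confidence-weight matrix from miRNA expression
#'
#' In the weighted factorization loss every matrix entry (i, j) carries a
#' weight w_ij. Observed associations (y_ij = 1) get full weight 1.
#' Unobserved entries get the miRNA's min-max-normalized expression value,
#' expressing how much confidence to place in the zero: a 0 in the
#' association matrix may simply be an undiscovered link, and expression is
#' used as auxiliary evidence. Normalization is global over all raw values
#' in the table.
#'
#' @param assoc binary association matrix (miRNA x disease, dimnames set).
#' @param expr expression table as returned by [read_expression_table()],
#'   or any data.frame with columns `mirna`, `condition`, `value`. A
#'   per-miRNA value (condition NA) is broadcast across all diseases;
#'   per-(miRNA, condition) values fill only the matching disease column.
#' @param default_weight weight used for unobserved entries of miRNAs (or
#'   (miRNA, disease) cells) absent from the table. `NA` (the default
#'   `NULL` disables the fallback) makes a missing miRNA an error.
#' @return numeric matrix of weights in \[0, 1\], index-aligned with
#'   `assoc`, with 1 exactly on the support of `assoc`. The matrix carries
#'   an attribute `"unobs"`: the same weights *without* the observed-entry
#'   override, i.e. the weight any entry would get if its association were
#'   unknown. Cross-validation uses it to re-weight held-out entries.
#' @export
build_weight_matrix <- function(assoc, expr, default_weight = NULL) {
  check_assoc(assoc)
  stopifnot(is.data.frame(expr), all(c("mirna", "value") %in% names(expr)))
  if (is.null(expr$condition)) expr$condition <- NA_character_
  v <- expr$value
  if (any(!is.finite(v))) stop("non-finite expression values")
  rng <- range(v)
  if (rng[1L] == rng[2L])
    stop("degenerate normalization: all expression values identical")
  norm <- (v - rng[1L]) / (rng[2L] - rng[1L])

  p <- nrow(assoc); q <- ncol(assoc)
  base <- matrix(NA_real_, p, q, dimnames = dimnames(assoc))
  per_mirna <- is.na(expr$condition)
  if (any(per_mirna)) {
    idx <- match(rownames(assoc), expr$mirna[per_mirna])
    hit <- !is.na(idx)
    base[hit, ] <- norm[per_mirna][idx[hit]]
  }
  if (any(!per_mirna)) {
    sub <- expr[!per_mirna, , drop = FALSE]
    nsub <- norm[!per_mirna]
    keep <- sub$mirna %in% rownames(assoc) & sub$condition %in% colnames(assoc)
    if (any(keep))
      base[cbind(sub$mirna[keep], sub$condition[keep])] <- nsub[keep]
  }
  if (anyNA(base)) {
    missing_mirna <- rownames(assoc)[apply(is.na(base), 1L, any)]
    if (is.null(default_weight))
      stop("no expression value for miRNA(s): ",
           paste(utils::head(missing_mirna, 5L), collapse = ", "),
           "; supply default_weight to proceed")
    if (!is.numeric(default_weight) || default_weight < 0 || default_weight > 1)
      stop("default_weight must lie in [0,1]")
    warning("filling ", sum(is.na(base)), " entries for ",
            length(missing_mirna), " miRNA(s) without expression with ",
            "default weight ", default_weight)
    base[is.na(base)] <- default_weight
  }
  w <- base
  w[assoc == 1L] <- 1
  attr(w, "unobs") <- base
  w
}
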