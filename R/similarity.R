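#' Semantic contributions of a disease's ancestors (Wang measure)
#'
#' For a disease D, each ancestor t in T(D) contributes
#' DD_D(t) = 1 if t = D, else max over children d' of t lying on a path
#' toward D of delta * DD_D(d'). The semantic value DV(D) is the sum of
#' contributions over T(D). Contributions therefore decay geometrically
#' with the shortest path distance from the ancestor to D.
#'
#' @param dag a [disease_dag()].
#' @param disease disease id present in the DAG.
#' @return list with `disease`, `contributions` (named numeric vector over
#'   T(D), each in (0, 1]) and `semantic_value` (DV, >= 1).
#' @export
semantic_contributions <- function(dag, disease) {
  anc <- dag_ancestors(dag, disease)
  dd <- stats::setNames(rep(NA_real_, length(anc)), anc)
  dd[[disease]] <- 1
  # Upward recursion restricted to T(D): repeatedly relax until fixed.
  # T(D) is finite and acyclic, so at most length(anc) sweeps settle it.
  repeat {
    changed <- FALSE
    for (t in anc) {
      if (t == disease) next
      # children of t that lie in T(D) (paths toward D go through them)
      kids <- dag$edges[dag$edges[, 1L] == t, 2L]
      kids <- kids[kids %in% anc]
      val <- suppressWarnings(max(dag$delta * dd[kids], na.rm = TRUE))
      if (is.finite(val) && (is.na(dd[[t]]) || val > dd[[t]])) {
        dd[[t]] <- val
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (anyNA(dd)) stop("internal: unreachable ancestor in contribution pass")
  list(disease = disease, contributions = dd,
       semantic_value = sum(dd))
}

#' Semantic similarity between two diseases
#'
#' SS(d_i, d_j) = sum over shared ancestors t of (DD_i(t) + DD_j(t)),
#' divided by DV(i) + DV(j). Lies in \[0, 1\], equals 1 on the diagonal,
#' and equals 0 when the two diseases share no ancestor.
#'
#' @param dag a [disease_dag()].
#' @param d_i,d_j disease ids present in the DAG.
#' @return similarity value in \[0, 1\].
#' @export
semantic_similarity <- function(dag, d_i, d_j) {
  ci <- semantic_contributions(dag, d_i)
  cj <- semantic_contributions(dag, d_j)
  shared <- intersect(names(ci$contributions), names(cj$contributions))
  num <- sum(ci$contributions[shared]) + sum(cj$contributions[shared])
  clamp01(num / (ci$semantic_value + cj$semantic_value))
}

#' Semantic similarity matrix over a set of diseases
#'
#' Computes pairwise [semantic_similarity()] for the diseases in
#' `disease_ids` that are present in the DAG. Diseases absent from the DAG
#' get `NA` rows/columns: they have no defined semantic similarity, and the
#' integration step ([integrate_similarity()]) falls back to the GIP kernel
#' there.
#'
#' @param dag a [disease_dag()].
#' @param disease_ids ordered disease ids (typically
#'   `colnames(assoc)`).
#' @return symmetric matrix with unit diagonal on the covered block and
#'   `NA` where either disease is outside the DAG.
#' @export
semantic_similarity_matrix <- function(dag, disease_ids) {
  q <- length(disease_ids)
  ss <- matrix(NA_real_, q, q, dimnames = list(disease_ids, disease_ids))
  covered <- disease_ids[disease_ids %in% dag$nodes]
  contribs <- lapply(covered, semantic_contributions, dag = dag)
  names(contribs) <- covered
  for (a in seq_along(covered)) {
    for (b in seq_len(a)) {
      ci <- contribs[[a]]; cj <- contribs[[b]]
      shared <- intersect(names(ci$contributions), names(cj$contributions))
      val <- clamp01((sum(ci$contributions[shared]) +
                        sum(cj$contributions[shared])) /
                       (ci$semantic_value + cj$semantic_value))
      ss[covered[a], covered[b]] <- ss[covered[b], covered[a]] <- val
    }
  }
  ss
}

#' GIP kernel bandwidth from association profiles
#'
#' The Gaussian interaction profile kernel bandwidth r is the raw
#' bandwidth r' divided by the mean squared norm of the disease
#' interaction profiles (the columns of the association matrix):
#' r = r' / ((1/n_d) * sum_i ||IP(d_i)||^2).
#'
#' @param assoc binary association matrix.
#' @param r_prime raw bandwidth r' > 0 (default 1).
#' @return list with `r_prime`, `r` and `n_d`.
#' @export
gip_bandwidth <- function(assoc, r_prime = 1) {
  check_assoc(assoc)
  stopifnot(is.numeric(r_prime), r_prime > 0)
  norms2 <- colSums(assoc^2)
  m <- mean(norms2)
  if (m == 0) stop("zero mean profile norm: association matrix is all zero")
  list(r_prime = r_prime, r = r_prime / m, n_d = ncol(assoc))
}

#' GIP kernel similarity between disease interaction profiles
#'
#' GS(d_i, d_j) = exp(-r * ||IP(d_i) - IP(d_j)||^2) where IP(d) is the
#' binary column of the association matrix for disease d. Symmetric with
#' unit diagonal; values in (0, 1].
#'
#' @param assoc binary association matrix.
#' @param bandwidth result of [gip_bandwidth()] (or any list with a
#'   positive `r`).
#' @return symmetric q x q similarity matrix with disease dimnames.
#' @export
gip_similarity <- function(assoc, bandwidth = gip_bandwidth(assoc)) {
  check_assoc(assoc)
  r <- bandwidth$r
  stopifnot(is.numeric(r), r > 0)
  g <- crossprod(assoc)                      # q x q Gram of profiles
  n2 <- diag(g)
  d2 <- outer(n2, n2, "+") - 2 * g           # squared distances
  d2[d2 < 0] <- 0                            # rounding guard
  gs <- exp(-r * d2)
  gs <- (gs + t(gs)) / 2
  diag(gs) <- 1
  dimnames(gs) <- list(colnames(assoc), colnames(assoc))
  gs
}

#' Integrated disease similarity
#'
#' Combines semantic similarity (where defined) with the GIP kernel:
#' S_jk = SS_jk when the pair has semantic similarity, else GS_jk. By
#' default "has semantic similarity" means both diseases are present in
#' the DAG, i.e. the SS entry is not `NA`; `rule = "positive"` instead uses
#' the semantic value only where it is strictly positive.
#'
#' @param ss semantic similarity matrix (with `NA` outside DAG coverage),
#'   e.g. from [semantic_similarity_matrix()].
#' @param gs GIP similarity matrix, index-aligned with `ss`.
#' @param rule `"covered"` (default) or `"positive"`.
#' @return symmetric integrated similarity matrix, unit diagonal, values
#'   in \[0, 1\].
#' @export
integrate_similarity <- function(ss, gs, rule = c("covered", "positive")) {
  rule <- match.arg(rule)
  if (!identical(dim(ss), dim(gs)) ||
      !identical(dimnames(ss), dimnames(gs)))
    stop("semantic and GIP similarity matrices are not index-aligned")
  use_ss <- if (rule == "covered") !is.na(ss) else (!is.na(ss) & ss > 0)
  s <- gs
  s[use_ss] <- ss[use_ss]
  s <- (s + t(s)) / 2
  diag(s) <- 1
  clamp01(s)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
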