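#' Construct a disease DAG
#'
#' A disease hierarchy DAG(D) = (D, T(D), E(D)): nodes are disease ids,
#' directed edges point from general (parent) to specific (child) terms,
#' T(D) is the ancestor set of D including D itself. The semantic
#' contribution factor delta controls how fast an ancestor's contribution
#' decays with distance.
#'
#' @param edges two-column character matrix of (parent, child) edges; may
#'   have zero rows.
#' @param nodes character vector of node ids; defaults to the ids seen in
#'   `edges`. Ids in `nodes` but not in `edges` become isolated roots.
#' @param delta semantic contribution factor in (0, 1].
#' @return object of class `disease_dag`: list with `nodes`, `edges`
#'   (2-column matrix), `parents` (named list: node -> character vector of
#'   parents) and `delta`.
#' @export
disease_dag <- function(edges, nodes = NULL, delta = 0.5) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta <= 0 || delta > 1)
    stop("delta must lie in (0, 1]")
  edges <- if (is.null(edges) || NROW(edges) == 0L) {
    matrix(character(0L), 0L, 2L)
  } else {
    matrix(as.character(as.matrix(edges)[, 1:2]), ncol = 2L)
  }
  nodes <- sort(unique(c(as.character(nodes), edges)))
  if (length(nodes) == 0L) stop("DAG has no nodes")
  if (any(edges[, 1L] == edges[, 2L]))
    stop("self-loop in DAG edge list")
  edges <- unique(edges)
  parents <- split(edges[, 1L], factor(edges[, 2L], levels = nodes))
  cyc <- find_cycle(nodes, parents)
  if (!is.null(cyc))
    stop("DAG contains a cycle: ", paste(cyc, collapse = " -> "))
  structure(list(nodes = nodes, edges = edges, parents = parents,
                 delta = delta),
            class = "disease_dag")
}

#' @export
print.disease_dag <- function(x, ...) {
  cat("disease_dag: ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges, delta = ", x$delta, "\n", sep = "")
  invisible(x)
}

#' Read a disease DAG from a file
#'
#' Two dialects: `"edges"` is a two-column tab-separated (parent, child)
#' edge list; `"treenum"` is a two-column (disease id, tree number) file in
#' the MeSH style, where dot-separated tree numbers like `C04.588` encode
#' the hierarchy and an edge is created from each tree-number prefix to its
#' one-level extension. A disease may carry several tree numbers (several
#' lines). Lines starting with '#' are ignored.
#'
#' @param path input file.
#' @param delta semantic contribution factor in (0, 1].
#' @param dialect `"edges"` or `"treenum"`.
#' @return a [disease_dag()].
#' @export
read_disease_dag <- function(path, delta = 0.5,
                             dialect = c("edges", "treenum")) {
  dialect <- match.arg(dialect)
  lines <- read_clean_lines(path)
  if (length(lines) == 0L) stop("empty DAG file '", path, "'")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L))
    stop("malformed DAG row at line ",
         attr(lines, "line_numbers")[which(nf < 2L)[1L]], " of '", path, "'")
  a <- vapply(fields, `[[`, character(1L), 1L)
  b <- vapply(fields, `[[`, character(1L), 2L)
  if (dialect == "edges")
    return(disease_dag(cbind(a, b), delta = delta))
  # treenum: map each tree number to its disease id, link prefix -> extension
  tn2id <- stats::setNames(a, b)
  parent_tn <- sub("\\.[^.]+$", "", b)
  has_parent <- parent_tn != b & parent_tn %in% names(tn2id)
  edges <- cbind(unname(tn2id[parent_tn[has_parent]]),
                 a[has_parent])
  edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]
  disease_dag(edges, nodes = unique(a), delta = delta)
}

#' Ancestor set T(D) of a disease
#'
#' All ancestors of `disease` in the DAG, including the disease itself.
#'
#' @param dag a [disease_dag()].
#' @param disease disease id.
#' @return character vector of ancestor ids (unordered).
#' @export
dag_ancestors <- function(dag, disease) {
  stopifnot(inherits(dag, "disease_dag"))
  if (!disease %in% dag$nodes)
    stop("disease '", disease, "' not in DAG")
  seen <- character(0L)
  frontier <- disease
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier],
                                      use.names = FALSE)), seen)
  }
  unique(seen)
}

# DFS cycle detection on the child -> parents map; returns one cycle as a
# vector of node ids, or NULL.
find_cycle <- function(nodes, parents) {
  color <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new 1 open 2 done
  stack <- character(0L)
  visit <- function(v) {
    color[[v]] <<- 1L
    stack <<- c(stack, v)
    for (u in parents[[v]]) {
      if (color[[u]] == 1L) {
        i <- match(u, stack)
        return(c(stack[seq(i, length(stack))], u))
      }
      if (color[[u]] == 0L) {
        cyc <- visit(u)
        if (!is.null(cyc)) return(cyc)
      }
    }
    color[[v]] <<- 2L
    stack <<- stack[-length(stack)]
    NULL
  }
  for (v in nodes) {
    if (color[[v]] == 0L) {
      cyc <- visit(v)
      if (!is.null(cyc)) return(cyc)
    }
  }
  NULL
}
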