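#' Generate a planted low-rank synthetic dataset
#'
#' Emulates the statistical structure the factorization model assumes:
#' nonnegative rank-`k` true factors, a binary association matrix whose
#' ones sit on the largest entries of the (noisy) true score matrix, a
#' disease similarity matrix that is the exact pairwise cosine of the true
#' disease factors, and expression-derived confidence weights correlated
#' with the true scores. Everything is reproducible from `seed`.
#'
#' @param p,q numbers of miRNAs and diseases.
#' @param k planted latent dimension.
#' @param density fraction of the p*q entries planted as known
#'   associations, in (0, 1); `ceiling(density * p * q)` ones are planted.
#' @param noise standard deviation of the Gaussian noise added to the true
#'   scores before thresholding (0 = noiseless planting).
#' @param seed integer seed.
#' @param expr_signal weight of the true scores in the synthetic
#'   expression draw, in \[0, 1\]; see [generate_expression()].
#' @return list of class `mdmf_synth`: `assoc`, `weights` (with the
#'   `"unobs"` attribute used by [mdmf_loocv()]), `sim`, `dag` (a small
#'   random hierarchy over the disease ids), `true_M`, `true_D`, `seed`
#'   and `params`.
#' @export
generate_planted <- function(p = 100L, q = 40L, k = 5L, density = 0.05,
                             noise = 0.1, seed = 1L, expr_signal = 0.3) {
  if (!is.numeric(density) || density <= 0 || density >= 1)
    stop("density must lie in (0, 1)")
  n_ones <- ceiling(density * p * q)
  if (n_ones < 2L) stop("density * p * q must be at least 2")
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)

  mirna_ids <- sprintf("miR-%03d", seq_len(p))
  disease_ids <- sprintf("D%03d", seq_len(q))
  true_M <- matrix(stats::runif(k * p), k, p, dimnames = list(NULL, mirna_ids))
  true_D <- matrix(stats::runif(k * q), k, q,
                   dimnames = list(NULL, disease_ids))
  truth <- crossprod(true_M, true_D)
  noisy <- truth + noise * stats::rnorm(p * q)
  y <- matrix(0L, p, q, dimnames = list(mirna_ids, disease_ids))
  y[order(noisy, decreasing = TRUE)[seq_len(n_ones)]] <- 1L

  nD <- sqrt(colSums(true_D^2))
  sim <- clamp01(crossprod(true_D) / outer(nD, nD))
  sim <- (sim + t(sim)) / 2
  diag(sim) <- 1
  dimnames(sim) <- list(disease_ids, disease_ids)

  expr <- generate_expression(p, q, signal = expr_signal,
                              seed = seed + 1L, truth = truth)
  weights <- build_weight_matrix(y, expr)
  dag <- generate_random_dag(q, layers = max(2L, min(4L, q %/% 3L)),
                             branching = 2L, seed = seed + 2L,
                             ids = disease_ids)

  structure(list(assoc = y, weights = weights, sim = sim, dag = dag,
                 true_M = true_M, true_D = true_D, seed = as.integer(seed),
                 params = list(p = p, q = q, k = k, density = density,
                               noise = noise, expr_signal = expr_signal)),
            class = "mdmf_synth")
}

#' Generate a random layered DAG
#'
#' Nodes are assigned to `layers` layers (layer 1 = roots); every node
#' below the first layer receives between 1 and `branching` parents drawn
#' from the layer directly above. The construction is acyclic by design
#' and every node is reachable from a root.
#'
#' @param n number of nodes.
#' @param layers number of layers; `layers = 1` gives n isolated roots.
#' @param branching maximum parents per non-root node.
#' @param seed integer seed.
#' @param delta semantic contribution factor for the resulting DAG.
#' @param ids optional character vector of node ids (length n); defaults
#'   to `D001..`.
#' @return a [disease_dag()].
#' @export
generate_random_dag <- function(n, layers = 3L, branching = 2L, seed = 1L,
                                delta = 0.5, ids = NULL) {
  stopifnot(n >= 1L, layers >= 1L, branching >= 1L)
  if (layers > n) stop("cannot fill ", layers, " layers with ", n, " nodes")
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)
  if (is.null(ids)) ids <- sprintf("D%03d", seq_len(n))
  stopifnot(length(ids) == n)
  # every layer gets at least one node; remaining nodes spread at random
  layer_of <- integer(n)
  layer_of[seq_len(layers)] <- seq_len(layers)
  if (n > layers)
    layer_of[(layers + 1L):n] <- sample.int(layers, n - layers,
                                            replace = TRUE)
  edges <- NULL
  if (layers > 1L) {
    for (v in which(layer_of > 1L)) {
      above <- which(layer_of == layer_of[v] - 1L)
      np <- sample.int(min(branching, length(above)), 1L)
      par <- if (length(above) == 1L) above else sample(above, np)
      edges <- rbind(edges, cbind(ids[par], ids[v]))
    }
  }
  disease_dag(edges, nodes = ids, delta = delta)
}

#' Generate a synthetic miRNA expression table
#'
#' Per-(miRNA, disease) expression values that are a convex mix of the
#' (min-max-normalized) true score matrix and uniform noise:
#' `value = signal * truth + (1 - signal) * noise`. At `signal = 0` the
#' expression carries no information about the truth; at `signal = 1` it
#' is a monotone transform of it.
#'
#' @param p,q numbers of miRNAs and diseases (must match `truth` if
#'   supplied).
#' @param signal mixing weight in \[0, 1\].
#' @param seed integer seed.
#' @param truth optional p x q true score matrix; required when
#'   `signal > 0`.
#' @return expression table data.frame (`mirna`, `condition`, `value`) in
#'   the three-column dialect of [read_expression_table()], values in
#'   \[0, 1\].
#' @export
generate_expression <- function(p, q, signal = 0.3, seed = 1L,
                                truth = NULL) {
  if (!is.numeric(signal) || signal < 0 || signal > 1)
    stop("signal must lie in [0, 1]")
  if (signal > 0 && is.null(truth))
    stop("truth matrix required when signal > 0")
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)
  mirna_ids <- if (!is.null(truth) && !is.null(rownames(truth)))
    rownames(truth) else sprintf("miR-%03d", seq_len(p))
  disease_ids <- if (!is.null(truth) && !is.null(colnames(truth)))
    colnames(truth) else sprintf("D%03d", seq_len(q))
  tnorm <- if (is.null(truth)) {
    matrix(0, p, q)
  } else {
    stopifnot(identical(dim(truth), c(as.integer(p), as.integer(q))))
    rng <- range(truth)
    if (rng[1L] == rng[2L]) matrix(0.5, p, q)
    else (truth - rng[1L]) / (rng[2L] - rng[1L])
  }
  vals <- signal * tnorm + (1 - signal) * stats::runif(p * q)
  rng <- range(vals)
  vals <- if (rng[1L] == rng[2L]) vals else
    (vals - rng[1L]) / (rng[2L] - rng[1L])
  data.frame(mirna = rep(mirna_ids, times = q),
             condition = rep(disease_ids, each = p),
             value = as.vector(vals),
             stringsAsFactors = FALSE)
}

#' Write the synthetic dataset as the package's input files
#'
#' Emits the three tab-separated files the readers understand — the
#' association pair list, the expression table and the DAG edge list —
#' plus a truth-score table for tests.
#'
#' @param synth a [generate_planted()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the four file paths, invisibly.
#' @export
write_synthetic_inputs <- function(synth, dir) {
  stopifnot(inherits(synth, "mdmf_synth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(associations = file.path(dir, "associations.tsv"),
             expression = file.path(dir, "expression.tsv"),
             dag = file.path(dir, "disease_dag.tsv"),
             truth = file.path(dir, "truth_scores.tsv"))
  write_association_pairs(synth$assoc, paths[["associations"]])
  expr <- generate_expression(synth$params$p, synth$params$q,
                              signal = synth$params$expr_signal,
                              seed = synth$seed + 1L,
                              truth = crossprod(synth$true_M, synth$true_D))
  utils::write.table(expr, paths[["expression"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(synth$dag$edges, paths[["dag"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_similarity_matrix(crossprod(synth$true_M, synth$true_D),
                          paths[["truth"]])
  invisible(paths)
}
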