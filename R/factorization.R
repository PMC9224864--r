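#' Training configuration for the similarity-constrained factorization
#'
#' Collects the hyperparameters of the weighted matrix-factorization model.
#' `alpha` trades off reconstruction of the association matrix against the
#' disease-similarity constraint: at `alpha = 0` the model is plain
#' weighted MF; large `alpha` lets the integrated disease similarity
#' dominate the disease latent space. The remaining parameters are the
#' usual MF knobs.
#'
#' @param k latent dimension (columns of the score model), >= 1.
#' @param alpha similarity-constraint trade-off, >= 0.
#' @param lambda1,lambda2 Frobenius regularization of the miRNA and disease
#'   latent matrices, >= 0.
#' @param eta gradient-descent learning rate, > 0.
#' @param max_epochs maximum number of full-batch epochs.
#' @param tol stopping tolerance on the relative objective decrease.
#' @param seed integer seed for the latent-factor initialization.
#' @param init_scale scale of the uniform (0, init_scale] initialization;
#'   strictly positive so no disease column starts at zero (the cosine in
#'   the constraint must be defined).
#' @return list of class `mdmf_config`.
#' @export
mdmf_config <- function(k = 40, alpha = 0.7, lambda1 = 0.01, lambda2 = 0.01,
                        eta = 0.01, max_epochs = 500, tol = 1e-6,
                        seed = 1L, init_scale = 0.1) {
  cfg <- list(k = as.integer(k), alpha = alpha, lambda1 = lambda1,
              lambda2 = lambda2, eta = eta,
              max_epochs = as.integer(max_epochs), tol = tol,
              seed = as.integer(seed), init_scale = init_scale)
  with(cfg, {
    stopifnot(k >= 1L, alpha >= 0, lambda1 >= 0, lambda2 >= 0,
              eta > 0, max_epochs >= 1L, tol >= 0, init_scale > 0)
  })
  structure(cfg, class = "mdmf_config")
}

# Column norms with a floor so the cosine stays defined if a disease
# column collapses toward zero during training.
.norm_floor <- 1e-12
guarded_colnorms <- function(D) {
  n <- sqrt(colSums(D^2))
  small <- n < .norm_floor
  if (any(small)) {
    warning(sum(small), " disease latent column(s) have near-zero norm; ",
            "flooring the cosine denominator")
    n[small] <- n[small] + .norm_floor
  }
  n
}

# Cosine-similarity matrix of the columns of D (q x q).
latent_cosine <- function(D, norms = guarded_colnorms(D)) {
  crossprod(D) / outer(norms, norms)
}

#' Objective of the similarity-constrained weighted factorization
#'
#' L = 1/2 \{ sum_ij w_ij (r_ij - d_j' m_i)^2
#'          + alpha * sum_(j<k) (S_jk - cos(d_j, d_k))^2
#'          + lambda1 ||M||_F^2 + lambda2 ||D||_F^2 \}
#'
#' where r is the binary association matrix, w the confidence weights, and
#' S the integrated disease similarity. The constraint term penalizes the
#' squared deviation of the disease latent cosine from S over unordered
#' disease pairs.
#'
#' @param M k x p miRNA latent matrix (column i = m_i).
#' @param D k x q disease latent matrix (column j = d_j).
#' @param assoc binary association matrix (p x q).
#' @param weights weight matrix (p x q).
#' @param sim integrated disease similarity matrix (q x q).
#' @param cfg [mdmf_config()].
#' @return nonnegative scalar.
#' @export
mdmf_objective <- function(M, D, assoc, weights, sim, cfg) {
  resid <- crossprod(M, D) - assoc            # p x q, pred - r
  data_term <- sum(weights * resid^2)
  cons_term <- 0
  if (cfg$alpha > 0) {
    n <- sqrt(colSums(D^2))
    if (any(n < .norm_floor)) stop("undefined cosine: zero disease column")
    dev <- sim - latent_cosine(D, n)
    cons_term <- sum(dev[upper.tri(dev)]^2)
  }
  0.5 * (data_term + cfg$alpha * cons_term +
           cfg$lambda1 * sum(M^2) + cfg$lambda2 * sum(D^2))
}

# Vectorized gradients; the exported per-index forms below slice these.
grad_M_all <- function(M, D, assoc, weights, cfg) {
  resid <- crossprod(M, D) - assoc
  D %*% t(weights * resid) + cfg$lambda1 * M
}

grad_D_all <- function(M, D, assoc, weights, sim, cfg) {
  resid <- crossprod(M, D) - assoc
  g <- M %*% (weights * resid) + cfg$lambda2 * D
  if (cfg$alpha > 0) {
    n <- guarded_colnorms(D)
    gram <- crossprod(D)
    cosmat <- gram / outer(n, n)
    A <- cfg$alpha * (sim - cosmat)
    diag(A) <- 0
    # d cos(d_j,d_k)/d d_j = d_k/(n_j n_k) - (d_j.d_k) d_j/(n_j^3 n_k);
    # gradient of the squared deviation sums over k != j with a minus sign.
    B <- A / outer(n, n)
    cvec <- rowSums(A * gram / outer(n^3, n))
    g <- g - (D %*% B - sweep(D, 2L, cvec, `*`))
  }
  g
}

#' Gradient of the objective in one miRNA latent vector
#'
#' d L / d m_i = sum_j w_ij (d_j' m_i - r_ij) d_j + lambda1 m_i.
#'
#' @inheritParams mdmf_objective
#' @param i miRNA index (1-based row of `assoc`).
#' @return length-k numeric vector.
#' @export
grad_mirna <- function(M, D, assoc, weights, cfg, i) {
  stopifnot(i >= 1L, i <= nrow(assoc))
  resid_i <- drop(crossprod(D, M[, i])) - assoc[i, ]
  drop(D %*% (weights[i, ] * resid_i)) + cfg$lambda1 * M[, i]
}

#' Gradient of the objective in one disease latent vector
#'
#' d L / d d_j = sum_i w_ij (d_j' m_i - r_ij) m_i + lambda2 d_j
#'             - alpha * sum_(k != j) (S_jk - cos(d_j, d_k)) *
#'               d cos(d_j, d_k) / d d_j.
#'
#' @inheritParams mdmf_objective
#' @param j disease index (1-based column of `assoc`).
#' @return length-k numeric vector.
#' @export
grad_disease <- function(M, D, assoc, weights, sim, cfg, j) {
  stopifnot(j >= 1L, j <= ncol(assoc))
  resid_j <- drop(crossprod(M, D[, j])) - assoc[, j]
  g <- drop(M %*% (weights[, j] * resid_j)) + cfg$lambda2 * D[, j]
  if (cfg$alpha > 0) {
    n <- guarded_colnorms(D)
    dj <- D[, j]
    for (kk in seq_len(ncol(D))) {
      if (kk == j) next
      dk <- D[, kk]
      dot <- sum(dj * dk)
      cosv <- dot / (n[j] * n[kk])
      dcos <- dk / (n[j] * n[kk]) - dot * dj / (n[j]^3 * n[kk])
      g <- g - cfg$alpha * (sim[j, kk] - cosv) * dcos
    }
  }
  g
}

#' Train the similarity-constrained weighted factorization
#'
#' Initializes both latent matrices i.i.d. uniform on (0, init_scale]
#' under `cfg$seed`, then runs full-batch gradient descent: every epoch
#' all miRNA and disease columns are updated simultaneously by
#' `- eta * gradient` evaluated at the current factors. Stops at
#' `max_epochs` or when the relative objective decrease drops below
#' `cfg$tol`.
#'
#' @inheritParams mdmf_objective
#' @param assoc binary association matrix (p x q, dimnames set).
#' @return object of class `mdmf_fit`: list with `M` (k x p), `D` (k x q),
#'   `objective` (numeric vector, value after each epoch, preceded by the
#'   initial value), `epochs` run, `converged` flag and `config`.
#' @export
mdmf_train <- function(assoc, weights, sim, cfg = mdmf_config()) {
  # the optimizer itself accepts any finite target matrix (binary in the
  # association use case); strict 0/1 validation lives in the IO layer
  stopifnot(is.matrix(assoc), all(is.finite(assoc)))
  if (is.null(rownames(assoc)) || is.null(colnames(assoc)))
    stop("target matrix must carry miRNA rownames and disease colnames")
  p <- nrow(assoc); q <- ncol(assoc)
  stopifnot(identical(dim(weights), c(p, q)),
            identical(dim(sim), c(q, q)))
  weights <- strip_attrs(weights)
  assoc_num <- strip_attrs(assoc) + 0.0
  k <- cfg$k

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(cfg$seed)
  # uniform (0, init_scale]: strictly positive so cosines are defined
  M <- matrix(cfg$init_scale * (1 - stats::runif(k * p)), k, p)
  D <- matrix(cfg$init_scale * (1 - stats::runif(k * q)), k, q)

  obj <- numeric(cfg$max_epochs + 1L)
  obj[1L] <- mdmf_objective(M, D, assoc_num, weights, sim, cfg)
  epochs <- 0L
  converged <- FALSE
  for (e in seq_len(cfg$max_epochs)) {
    gM <- grad_M_all(M, D, assoc_num, weights, cfg)
    gD <- grad_D_all(M, D, assoc_num, weights, sim, cfg)
    M <- M - cfg$eta * gM
    D <- D - cfg$eta * gD
    o <- mdmf_objective(M, D, assoc_num, weights, sim, cfg)
    if (!is.finite(o))
      stop("objective diverged at epoch ", e,
           "; try a smaller learning rate eta")
    epochs <- e
    obj[e + 1L] <- o
    rel <- (obj[e] - o) / max(obj[e], .Machine$double.eps)
    if (rel >= 0 && rel < cfg$tol) {
      converged <- TRUE
      break
    }
  }
  colnames(M) <- rownames(assoc)
  colnames(D) <- colnames(assoc)
  structure(list(M = M, D = D, objective = obj[seq_len(epochs + 1L)],
                 epochs = epochs, converged = converged, config = cfg),
            class = "mdmf_fit")
}

#' @export
print.mdmf_fit <- function(x, ...) {
  cat("mdmf_fit: k = ", x$config$k, ", ", ncol(x$M), " miRNAs x ",
      ncol(x$D), " diseases\n", sep = "")
  cat("  epochs: ", x$epochs, if (x$converged) " (converged)" else "",
      "; final objective: ", format(x$objective[length(x$objective)]),
      "\n", sep = "")
  invisible(x)
}

#' Predicted association scores
#'
#' The relatedness score of miRNA i and disease j is the dot product of
#' their latent vectors, m_i . d_j, i.e. the (i, j) entry of M'D.
#'
#' @param fit an `mdmf_fit` (or any list with k x p `M` and k x q `D`).
#' @return p x q numeric score matrix with the fit's dimnames.
#' @export
predict_scores <- function(fit) {
  crossprod(fit$M, fit$D)
}

strip_attrs <- function(x) {
  attr(x, "unobs") <- NULL
  x
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
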