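# Independent brute-force oracles. These deliberately avoid the package's
# own computation paths: path enumeration instead of recursion, explicit
# loops instead of matrix algebra, all-pairs counting instead of ranks.

# All directed paths t -> D following parent->child edges; returns the
# number of edges on each path. Exponential, fine for tiny DAGs.
enumerate_path_lengths <- function(edges, from, to) {
  if (from == to) return(0L)
  if (NROW(edges) == 0L) return(integer(0L))
  out <- integer(0L)
  kids <- edges[edges[, 1L] == from, 2L]
  for (kid in kids) out <- c(out, 1L + enumerate_path_lengths(edges, kid, to))
  out
}

# Wang semantic similarity by explicit path enumeration: the contribution
# of ancestor t to disease D is delta^(shortest path length t -> D), since
# each recursion step multiplies by delta and the max picks the shortest
# chain.
oracle_contributions <- function(dag, disease) {
  anc <- character(0L)
  for (n in dag$nodes) {
    if (n == disease || length(enumerate_path_lengths(dag$edges, n, disease)))
      anc <- c(anc, n)
  }
  dd <- vapply(anc, function(t) {
    if (t == disease) return(1)
    dag$delta^min(enumerate_path_lengths(dag$edges, t, disease))
  }, numeric(1L))
  list(contributions = dd, semantic_value = sum(dd))
}

oracle_semantic_similarity <- function(dag, d_i, d_j) {
  ci <- oracle_contributions(dag, d_i)
  cj <- oracle_contributions(dag, d_j)
  shared <- intersect(names(ci$contributions), names(cj$contributions))
  (sum(ci$contributions[shared]) + sum(cj$contributions[shared])) /
    (ci$semantic_value + cj$semantic_value)
}

# All-pairs AUC: count wins and half-ties over every (positive, negative)
# pair.
oracle_auc <- function(pos, neg) {
  wins <- 0
  for (a in pos) for (b in neg) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  wins / (length(pos) * length(neg))
}

# Average precision by walking the sorted list one distinct score at a
# time with explicit confusion recounts.
oracle_aupr <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels)
  prev_rec <- 0; ap <- 0
  for (t in th) {
    tp <- sum(scores >= t & labels == 1)
    fp <- sum(scores >= t & labels == 0)
    rec <- tp / npos
    ap <- ap + (tp / (tp + fp)) * (rec - prev_rec)
    prev_rec <- rec
  }
  ap
}

oracle_confusion <- function(scores, labels, threshold) {
  tp <- fp <- tn <- fn <- 0
  for (idx in seq_along(scores)) {
    hit <- scores[idx] >= threshold
    if (hit && labels[idx] == 1) tp <- tp + 1
    if (hit && labels[idx] == 0) fp <- fp + 1
    if (!hit && labels[idx] == 0) tn <- tn + 1
    if (!hit && labels[idx] == 1) fn <- fn + 1
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Objective by direct term-by-term summation with scalar loops.
oracle_objective <- function(M, D, y, w, S, cfg) {
  p <- nrow(y); q <- ncol(y); total <- 0
  for (i in seq_len(p)) for (j in seq_len(q)) {
    total <- total + w[i, j] * (y[i, j] - sum(D[, j] * M[, i]))^2
  }
  if (cfg$alpha > 0) {
    for (j in seq_len(q - 1L)) for (kk in (j + 1L):q) {
      cosv <- sum(D[, j] * D[, kk]) /
        (sqrt(sum(D[, j]^2)) * sqrt(sum(D[, kk]^2)))
      total <- total + cfg$alpha * (S[j, kk] - cosv)^2
    }
  }
  total <- total + cfg$lambda1 * sum(M^2) + cfg$lambda2 * sum(D^2)
  0.5 * total
}

# Central finite differences of the objective in one miRNA / disease column.
fd_grad_mirna <- function(M, D, y, w, S, cfg, i, h = 1e-6) {
  vapply(seq_len(nrow(M)), function(r) {
    Mp <- M; Mm <- M
    Mp[r, i] <- Mp[r, i] + h; Mm[r, i] <- Mm[r, i] - h
    (mdmf_objective(Mp, D, y, w, S, cfg) -
       mdmf_objective(Mm, D, y, w, S, cfg)) / (2 * h)
  }, numeric(1L))
}

fd_grad_disease <- function(M, D, y, w, S, cfg, j, h = 1e-6) {
  vapply(seq_len(nrow(D)), function(r) {
    Dp <- D; Dm <- D
    Dp[r, j] <- Dp[r, j] + h; Dm[r, j] <- Dm[r, j] - h
    (mdmf_objective(M, Dp, y, w, S, cfg) -
       mdmf_objective(M, Dm, y, w, S, cfg)) / (2 * h)
  }, numeric(1L))
}

# Small random problem instance shared by several tests.
random_instance <- function(seed, p = 4L, q = 3L, k = 3L,
                            alpha = 0.7, lambda1 = 0.01, lambda2 = 0.02) {
  set.seed(seed)
  y <- matrix(rbinom(p * q, 1L, 0.4), p, q,
              dimnames = list(paste0("m", seq_len(p)),
                              paste0("d", seq_len(q))))
  w <- matrix(runif(p * q), p, q); w[y == 1L] <- 1
  D0 <- matrix(runif(k * q) + 0.1, k, q)
  n <- sqrt(colSums(D0^2))
  S <- crossprod(D0) / outer(n, n); diag(S) <- 1
  M <- matrix(runif(k * p) + 0.1, k, p)
  D <- matrix(runif(k * q) + 0.1, k, q)
  cfg <- mdmf_config(k = k, alpha = alpha, lambda1 = lambda1,
                     lambda2 = lambda2, seed = seed)
  list(y = y, w = w, S = S, M = M, D = D, cfg = cfg)
}

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
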