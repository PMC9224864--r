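test_that("objective matches hand cases and the term-enumeration oracle", {
  inst <- random_instance(1L)
  # M = 0 with alpha = lambda1 = lambda2 = 0 and r = 0: every term vanishes
  cfg0 <- mdmf_config(k = 3L, alpha = 0, lambda1 = 0, lambda2 = 0)
  expect_equal(mdmf_objective(inst$M * 0, inst$D, inst$y * 0L, inst$w,
                              inst$S, cfg0), 0)
  # one observed pair, unit weight, zero prediction: 1/2 * 1
  y1 <- matrix(1, 1L, 1L); w1 <- matrix(1, 1L, 1L)
  expect_equal(mdmf_objective(matrix(0, 2L, 1L), matrix(c(1, 1), 2L, 1L),
                              y1, w1, matrix(1, 1L, 1L), cfg0), 0.5)
  # random instances against the scalar-loop oracle
  for (seed in 1:5) {
    inst <- random_instance(seed, p = 3L, q = 3L, k = 3L)
    expect_equal(mdmf_objective(inst$M, inst$D, inst$y, inst$w, inst$S,
                                inst$cfg),
                 oracle_objective(inst$M, inst$D, inst$y, inst$w, inst$S,
                                  inst$cfg),
                 tolerance = 1e-10)
  }
})

test_that("analytic gradients match central finite differences", {
  for (seed in 1:20) {
    inst <- random_instance(seed, p = 5L, q = 4L, k = 3L,
                            alpha = runif(1L, 0, 1.5))
    for (i in c(1L, 3L)) {
      ga <- grad_mirna(inst$M, inst$D, inst$y, inst$w, inst$cfg, i)
      gn <- fd_grad_mirna(inst$M, inst$D, inst$y, inst$w, inst$S,
                          inst$cfg, i)
      expect_lt(max(abs(ga - gn) / pmax(abs(gn), 1e-6)), 1e-5)
    }
    for (j in c(1L, 4L)) {
      ga <- grad_disease(inst$M, inst$D, inst$y, inst$w, inst$S,
                         inst$cfg, j)
      gn <- fd_grad_disease(inst$M, inst$D, inst$y, inst$w, inst$S,
                            inst$cfg, j)
      expect_lt(max(abs(ga - gn) / pmax(abs(gn), 1e-6)), 1e-5)
    }
  }
})

test_that("gradient edge cases behave as stationarity predicts", {
  inst <- random_instance(2L)
  k <- 3L
  # exact factorization, no regularization: miRNA gradient vanishes
  M <- inst$M; D <- inst$D
  y_exact <- crossprod(M, D)
  cfg0 <- mdmf_config(k = k, alpha = 0, lambda1 = 0, lambda2 = 0)
  expect_equal(grad_mirna(M, D, y_exact, inst$w, cfg0, 2L), rep(0, k))
  # pure regularization: gradient is lambda1 * m_i
  cfg_reg <- mdmf_config(k = k, alpha = 0, lambda1 = 0.3, lambda2 = 0)
  expect_equal(grad_mirna(M, D, y_exact, inst$w, cfg_reg, 2L),
               0.3 * M[, 2L])
  # alpha = 0 disease gradient is the transposed-roles data term
  gd <- grad_disease(M, D, inst$y, inst$w, inst$S,
                     mdmf_config(k = k, alpha = 0, lambda1 = 0, lambda2 = 0),
                     2L)
  resid <- drop(crossprod(M, D[, 2L])) - inst$y[, 2L]
  expect_equal(gd, drop(M %*% (inst$w[, 2L] * resid)))
  # constraint exactly satisfied, no residuals: disease gradient vanishes
  S_cos <- {
    n <- sqrt(colSums(D^2))
    s <- crossprod(D) / outer(n, n); diag(s) <- 1; s
  }
  expect_equal(grad_disease(M, D, y_exact, inst$w, S_cos,
                            mdmf_config(k = k, alpha = 0.9, lambda1 = 0,
                                        lambda2 = 0), 2L),
               rep(0, k), tolerance = 1e-12)
})

test_that("the vectorized epoch gradients agree with the per-index forms", {
  inst <- random_instance(5L, p = 6L, q = 5L, k = 4L)
  gM <- mdmf:::grad_M_all(inst$M, inst$D, inst$y, inst$w, inst$cfg)
  gD <- mdmf:::grad_D_all(inst$M, inst$D, inst$y, inst$w, inst$S, inst$cfg)
  for (i in seq_len(ncol(inst$M)))
    expect_equal(gM[, i], grad_mirna(inst$M, inst$D, inst$y, inst$w,
                                     inst$cfg, i))
  for (j in seq_len(ncol(inst$D)))
    expect_equal(gD[, j], grad_disease(inst$M, inst$D, inst$y, inst$w,
                                       inst$S, inst$cfg, j))
})

test_that("training decreases the objective and is seed-deterministic", {
  inst <- random_instance(3L, p = 10L, q = 6L, k = 3L)
  cfg <- mdmf_config(k = 3L, alpha = 0.7, eta = 0.005, max_epochs = 50L,
                     tol = 0, seed = 42L)
  fit <- mdmf_train(inst$y, inst$w, inst$S, cfg)
  expect_true(all(diff(fit$objective) <= 1e-12))
  fit2 <- mdmf_train(inst$y, inst$w, inst$S, cfg)
  expect_identical(fit$M, fit2$M)
  expect_identical(fit$D, fit2$D)
  expect_identical(fit$objective, fit2$objective)
})

test_that("training does not disturb the caller's RNG stream", {
  inst <- random_instance(3L)
  set.seed(123)
  before <- runif(1L)
  set.seed(123)
  invisible(mdmf_train(inst$y, inst$w, inst$S,
                       mdmf_config(k = 3L, max_epochs = 2L, seed = 9L)))
  expect_identical(runif(1L), before)
})

test_that("a noiseless rank-2 matrix is recovered by unconstrained training", {
  set.seed(8)
  k <- 2L; p <- 20L; q <- 10L
  Mstar <- matrix(runif(k * p), k, p)
  Dstar <- matrix(runif(k * q), k, q)
  R <- crossprod(Mstar, Dstar)
  y <- R; dimnames(y) <- list(sprintf("m%d", 1:p), sprintf("d%d", 1:q))
  w <- matrix(1, p, q)
  cfg <- mdmf_config(k = k, alpha = 0, lambda1 = 0, lambda2 = 0,
                     eta = 0.01, max_epochs = 2000L, tol = 0, seed = 4L)
  fit <- mdmf_train(y, w, S_dummy <- diag(q), cfg)
  res0 <- fit$objective[1L]
  expect_lte(fit$objective[length(fit$objective)], 1e-3 * res0)
})

test_that("scores are the latent dot products and Gram-invariant at alpha 0", {
  inst <- random_instance(6L, p = 5L, q = 4L, k = 3L)
  fit <- list(M = inst$M, D = inst$D)
  sc <- predict_scores(fit)
  expect_equal(sc, crossprod(inst$M, inst$D))
  expect_equal(sc[2L, 3L], sum(inst$M[, 2L] * inst$D[, 3L]))
  # unit aligned / orthogonal vectors
  e1 <- c(1, 0, 0)
  expect_equal(unname(predict_scores(list(M = cbind(e1),
                                          D = cbind(e1)))[1L, 1L]), 1)
  expect_equal(unname(predict_scores(list(M = cbind(e1),
                                          D = cbind(c(0, 1, 0))))[1L, 1L]), 0)
  # simultaneous orthogonal rotation leaves the Gram matrix unchanged
  qr_rot <- qr.Q(qr(matrix(rnorm(9L), 3L)))
  expect_equal(predict_scores(list(M = qr_rot %*% inst$M,
                                   D = qr_rot %*% inst$D)), sc)
})

test_that("training with the similarity constraint pulls latent cosines toward S", {
  set.seed(21)
  k <- 3L; p <- 30L; q <- 12L
  Dstar <- matrix(runif(k * q) + 0.05, k, q)
  nD <- sqrt(colSums(Dstar^2))
  S <- crossprod(Dstar) / outer(nD, nD); diag(S) <- 1
  Mstar <- matrix(runif(k * p), k, p)
  scores <- crossprod(Mstar, Dstar)
  y <- matrix(0L, p, q, dimnames = list(sprintf("m%d", 1:p),
                                        sprintf("d%d", 1:q)))
  y[order(scores, decreasing = TRUE)[1:40]] <- 1L
  w <- matrix(1, p, q)
  gap <- function(alpha) {
    fit <- mdmf_train(y, w, S, mdmf_config(k = k, alpha = alpha,
                                           eta = 0.01, max_epochs = 300L,
                                           tol = 0, seed = 2L))
    n <- sqrt(colSums(fit$D^2))
    cosm <- crossprod(fit$D) / outer(n, n)
    mean(abs(S - cosm)[upper.tri(S)])
  }
  expect_lt(gap(0.7), gap(0))
})

test_that("divergent learning rates raise an informative error", {
  inst <- random_instance(4L, p = 8L, q = 5L, k = 3L)
  expect_error(mdmf_train(inst$y, inst$w, inst$S,
                          mdmf_config(k = 3L, eta = 50, max_epochs = 200L,
                                      seed = 1L)),
               "smaller learning rate")
})
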