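#' Area under the ROC curve from two score samples
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' positive outscores a randomly chosen negative, ties counting one half.
#' AUC = 1 means every positive outranks every negative; 0.5 is chance
#' level.
#'
#' @param positive_scores,negative_scores nonempty numeric vectors.
#' @return AUC in \[0, 1\].
#' @export
auc_from_ranks <- function(positive_scores, negative_scores) {
  if (length(positive_scores) == 0L || length(negative_scores) == 0L)
    stop("both score lists must be nonempty")
  np <- length(positive_scores); nn <- length(negative_scores)
  r <- rank(c(positive_scores, negative_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise integration over the score-sorted list: at each distinct
#' score threshold, precision times the recall increment accumulated at
#' that threshold. Tied scores enter the confusion counts as one block, so
#' the result does not depend on their input order.
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels, same length; at least one positive.
#' @return AUPR in \[0, 1\].
#' @export
aupr <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  npos <- sum(labels)
  if (npos == 0L) stop("no positive labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  blocks <- rle(s)$lengths
  tp <- 0; fp <- 0; ap <- 0
  at <- 0L
  for (len in blocks) {
    bp <- sum(l[at + seq_len(len)])
    tp <- tp + bp; fp <- fp + (len - bp)
    if (bp > 0) ap <- ap + (tp / (tp + fp)) * (bp / npos)
    at <- at + len
  }
  ap
}

#' Confusion-table metrics at a threshold
#'
#' Predictions are `score >= threshold`. Returns F1, accuracy and the
#' Matthews correlation coefficient from the resulting 2x2 table. When an
#' MCC denominator factor is zero the value 0 is returned (the usual
#' convention) with a message, unless `strict = TRUE`.
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels.
#' @param threshold decision threshold.
#' @param strict error instead of applying the MCC zero-denominator
#'   convention or accepting single-class labels.
#' @return named list: `f1`, `acc`, `mcc` (on the \[-1, 1\] scale).
#' @export
confusion_metrics <- function(scores, labels, threshold, strict = FALSE) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (strict && length(unique(labels)) < 2L)
    stop("labels contain a single class; MCC undefined")
  pred <- as.integer(scores >= threshold)
  tp <- as.numeric(sum(pred == 1 & labels == 1))
  fp <- as.numeric(sum(pred == 1 & labels == 0))
  tn <- as.numeric(sum(pred == 0 & labels == 0))
  fn <- as.numeric(sum(pred == 0 & labels == 1))
  acc <- (tp + tn) / length(labels)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) {
    if (strict) stop("MCC denominator is zero")
    message("MCC denominator zero; returning 0 by convention")
    0
  } else {
    (tp * tn - fp * fn) / sqrt(den)
  }
  list(f1 = f1, acc = acc, mcc = mcc)
}

# Sweep all distinct scores as thresholds, return metrics at the
# F1-maximizing one (ties broken toward the larger threshold). Cumulative
# counts over the sorted scores make the sweep linear after sorting.
best_threshold_metrics <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  last <- cumsum(rle(s)$lengths)          # index of last element per level
  tp <- cumsum(l)[last]
  fp <- cumsum(1 - l)[last]
  f1 <- ifelse(2 * tp + fp + (sum(l) - tp) == 0, 0,
               2 * tp / (2 * tp + fp + (sum(l) - tp)))
  pick <- which.max(f1)                   # first (largest) threshold wins ties
  th <- s[last][pick]
  m <- suppressMessages(confusion_metrics(scores, labels, th))
  m$threshold_used <- th
  m
}

#' Leave-one-out cross-validation of the factorization
#'
#' Each known association (a 1 in the matrix) is held out in turn: its
#' entry is set to 0, its weight is replaced by the unobserved-entry
#' weight (the `"unobs"` attribute of the weight matrix; 0 if absent), the
#' model is retrained from the same seeded initialization, and the
#' held-out pair's score is ranked among the candidate pairs of that fold.
#' Under the global protocol the candidates are all zero entries of the
#' fold's training matrix across every disease; under the local protocol
#' only the zero entries in the held-out pair's disease column.
#'
#' The AUC pools, across folds, each fold's held-out score (positive)
#' against that fold's candidate scores (negatives). AUPR, F1, accuracy
#' and MCC are computed on the same pooled scores, with F1/ACC/MCC taken
#' at the F1-maximizing threshold over all distinct pooled scores
#' (reported as `threshold_used`).
#'
#' @param assoc binary association matrix.
#' @param weights weight matrix from [build_weight_matrix()] (its
#'   `"unobs"` attribute supplies held-out entry weights).
#' @param sim integrated disease similarity matrix.
#' @param cfg [mdmf_config()]; every fold retrains with `cfg$seed`.
#' @param protocol `"global"` or `"local"`.
#' @param n_folds optional cap on the number of held-out pairs; when
#'   smaller than the number of known associations, that many pairs are
#'   sampled without replacement (seeded by `fold_seed`).
#' @param fold_seed seed for the fold subsample.
#' @param scorer optional function `(assoc_train, weights_train) ->
#'   score matrix` replacing factorization training; used for oracle
#'   checks and custom models.
#' @return list with `folds` (data.frame: mirna, disease, rank,
#'   candidates, score) and `report` (list: auc, aupr, f1, acc, mcc,
#'   threshold_used, protocol).
#' @export
mdmf_loocv <- function(assoc, weights, sim, cfg = mdmf_config(),
                       protocol = c("global", "local"),
                       n_folds = NULL, fold_seed = cfg$seed,
                       scorer = NULL) {
  protocol <- match.arg(protocol)
  check_assoc(assoc)
  known <- which(assoc == 1L, arr.ind = TRUE)
  known <- known[order(known[, 1L], known[, 2L]), , drop = FALSE]
  if (nrow(known) < 2L) stop("need at least 2 known associations for LOOCV")
  unobs <- attr(weights, "unobs")
  if (is.null(unobs)) unobs <- matrix(0, nrow(assoc), ncol(assoc))

  if (!is.null(n_folds) && n_folds < nrow(known)) {
    old_seed <- get_rng_state()
    on.exit(restore_rng_state(old_seed), add = TRUE)
    set.seed(fold_seed)
    known <- known[sort(sample.int(nrow(known), n_folds)), , drop = FALSE]
  }

  res <- vector("list", nrow(known))
  pos_scores <- numeric(nrow(known))
  neg_scores <- vector("list", nrow(known))
  for (f in seq_len(nrow(known))) {
    i <- known[f, 1L]; j <- known[f, 2L]
    a <- assoc; a[i, j] <- 0L
    w <- strip_attrs(weights); w[i, j] <- unobs[i, j]
    scores <- if (is.null(scorer)) {
      predict_scores(mdmf_train(a, w, sim, cfg))
    } else {
      scorer(a, w)
    }
    if (protocol == "global") {
      cand <- which(a == 0L)
      cand_scores <- scores[cand]
      held <- scores[i, j]
      others <- cand_scores[cand != (j - 1L) * nrow(a) + i]
    } else {
      cand <- which(a[, j] == 0L)
      cand_scores <- scores[cand, j]
      held <- scores[i, j]
      others <- cand_scores[cand != i]
    }
    if (length(others) == 0L) {
      warning("fold (", rownames(assoc)[i], ", ", colnames(assoc)[j],
              ") has no candidate negatives; skipped")
      res[[f]] <- NULL
      pos_scores[f] <- NA_real_
      next
    }
    # midrank among candidates (held-out pair included in the universe)
    rk <- 1 + sum(others > held) + sum(others == held) / 2
    res[[f]] <- data.frame(
      mirna = rownames(assoc)[i], disease = colnames(assoc)[j],
      rank = rk, candidates = length(others) + 1L, score = held,
      stringsAsFactors = FALSE)
    pos_scores[f] <- held
    neg_scores[[f]] <- others
  }
  keep <- !is.na(pos_scores)
  folds <- do.call(rbind, res[keep])
  pos <- pos_scores[keep]
  neg <- unlist(neg_scores[keep], use.names = FALSE)
  pooled_scores <- c(pos, neg)
  pooled_labels <- c(rep(1, length(pos)), rep(0, length(neg)))
  best <- best_threshold_metrics(pooled_scores, pooled_labels)
  report <- list(
    auc = auc_from_ranks(pos, neg),
    aupr = aupr(pooled_scores, pooled_labels),
    f1 = best$f1, acc = best$acc, mcc = best$mcc,
    threshold_used = best$threshold_used,
    protocol = protocol)
  list(folds = folds, report = report)
}

#' Rank candidate miRNAs for a disease
#'
#' Returns the miRNAs *not* yet known to be associated with the queried
#' disease, ordered by predicted relatedness score (descending); ties are
#' broken by miRNA id ascending so the ranking is deterministic.
#'
#' @param scores p x q score matrix (e.g. from [predict_scores()]),
#'   index-aligned with `assoc`.
#' @param assoc binary association matrix.
#' @param disease disease id (must be a column of `assoc`).
#' @param top_n number of candidates to return; capped at the number of
#'   available candidates.
#' @return data.frame with columns `mirna` and `score`, `top_n` rows.
#' @export
rank_candidates <- function(scores, assoc, disease, top_n = 50L) {
  check_assoc(assoc)
  if (!disease %in% colnames(assoc))
    stop("unknown disease id '", disease, "'")
  cand <- which(assoc[, disease] == 0L)
  s <- scores[cand, disease]
  ids <- rownames(assoc)[cand]
  ord <- order(-s, ids)
  n <- min(top_n, length(cand))
  data.frame(mirna = ids[ord][seq_len(n)], score = s[ord][seq_len(n)],
             row.names = NULL, stringsAsFactors = FALSE)
}
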