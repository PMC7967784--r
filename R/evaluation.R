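#' Assign records to cross-validation folds
#'
#' Seeded shuffle followed by round-robin assignment into `k` folds, so fold
#' sizes differ by at most one. With `stratify = TRUE` the round-robin runs
#' within each underlying-cause label group (groups laid out consecutively,
#' the robin continuing across group boundaries), so rare causes are spread
#' across folds while the global size balance is preserved.
#'
#' @param records a `death_records` data frame.
#' @param k number of folds (default 17).
#' @param seed integer seed; identical seeds give identical assignments.
#' @param stratify spread underlying-cause labels across folds.
#' @return a `fold_assignment`: list with `k`, `seed`, and `fold`, a named
#'   integer vector mapping `record_id` to a fold index in `1..k`.
#' @export
kfold_split <- function(records, k = 17L, seed = 1L, stratify = FALSE) {
  n <- nrow(records)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("k exceeds the number of records", call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  if (stratify) {
    perm <- perm[order(records$underlying[perm], method = "radix")]
  }
  fold <- integer(n)
  fold[perm] <- ((seq_len(n) - 1L) %% k) + 1L
  structure(list(k = k, seed = as.integer(seed),
                 fold = stats::setNames(fold, records$record_id)),
            class = "fold_assignment")
}

#' Per-cause classification metrics
#'
#' One-vs-rest precision, recall and F1 per underlying cause, with macro
#' (unweighted mean over causes present in the truth) and micro aggregates.
#' In this single-label, single-prediction setting the micro-averaged
#' precision, recall and F1 all equal the overall accuracy. Undefined
#' ratios (zero denominators) are reported as 0.
#'
#' @param truth character vector of labeled underlying causes.
#' @param predicted character vector of predictions, same length.
#' @param thresholds F1 thresholds for the exceedance-fraction summary.
#' @return an `evaluation_report`: list with `per_cause` (data frame
#'   `cause, precision, recall, f1, support`), `macro_precision`,
#'   `macro_recall`, `macro_f1`, `micro_precision`, `micro_recall`,
#'   `micro_f1`, `f1_fraction_above` (named numeric vector) and `n`.
#' @export
classification_report <- function(truth, predicted,
                                  thresholds = c(0.5, 0.7, 0.9, 0.95)) {
  stopifnot(length(truth) == length(predicted), length(truth) > 0L)
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  causes <- sort(unique(truth), method = "radix")
  tp <- vapply(causes, function(u) sum(truth == u & predicted == u), 0)
  fp <- vapply(causes, function(u) sum(truth != u & predicted == u), 0)
  fn <- vapply(causes, function(u) sum(truth == u & predicted != u), 0)
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  per_cause <- data.frame(cause = causes, precision = precision,
                          recall = recall, f1 = f1,
                          support = as.integer(tapply(truth, truth, length)[causes]),
                          stringsAsFactors = FALSE, row.names = NULL)
  acc <- mean(truth == predicted)
  report <- list(per_cause = per_cause,
                 macro_precision = mean(precision),
                 macro_recall = mean(recall),
                 macro_f1 = mean(f1),
                 micro_precision = acc, micro_recall = acc, micro_f1 = acc,
                 n = length(truth))
  report$f1_fraction_above <- stats::setNames(
    vapply(thresholds, function(t) mean(per_cause$f1 > t), 0),
    format(thresholds))
  class(report) <- "evaluation_report"
  report
}

#' Fraction of causes with F1 above thresholds
#'
#' For each threshold, the fraction of causes (with support >= 1) whose F1
#' exceeds it. Non-increasing in the threshold.
#'
#' @param report an `evaluation_report`.
#' @param thresholds numeric vector of thresholds.
#' @return named numeric vector of fractions.
#' @export
f1_distribution <- function(report, thresholds = c(0.5, 0.7, 0.9, 0.95)) {
  stopifnot(inherits(report, "evaluation_report"))
  pc <- report$per_cause[report$per_cause$support >= 1L, , drop = FALSE]
  if (!nrow(pc)) stop("report has no per-cause entries", call. = FALSE)
  stats::setNames(vapply(thresholds, function(t) mean(pc$f1 > t), 0),
                  format(thresholds))
}

#' Cross-validate an inference method
#'
#' k-fold cross-validation of the sink algorithm (or a reference baseline):
#' for each fold, the estimator is fitted on the other k-1 folds only (no
#' leakage of test-fold counts) and run on the held-out fold. Held-out
#' predictions are pooled over all folds before computing per-cause
#' metrics, which keeps metrics for rare causes defined; per-fold averaged
#' macro/micro aggregates are additionally reported under `per_fold` when
#' `aggregate = "per_fold"`.
#'
#' @param records labeled `death_records`.
#' @param k,seed,stratify fold assignment, see [kfold_split()].
#' @param method `"sink"` (default), `"nb"` or `"knn"`.
#' @param transform,smoothing_alpha CDCP estimator settings (sink only).
#' @param external_rule,include_history,fallback_policy inference options
#'   (sink only), see [sink_infer_batch()].
#' @param nb_alpha additive smoothing for the naive Bayes baseline.
#' @param nb_restrict restrict naive Bayes to the record's candidate set.
#' @param knn_k neighbourhood size for the KNN baseline.
#' @param aggregate `"pooled"` (default) or `"per_fold"`.
#' @param thresholds F1 thresholds for the exceedance summary.
#' @return an `evaluation_report` (see [classification_report()]) with
#'   extra fields `method`, `k`, `seed`, and `predictions` (pooled held-out
#'   predictions in input record order).
#' @export
cross_validate <- function(records, k = 17L, seed = 1L,
                           method = c("sink", "nb", "knn"),
                           transform = c("raw", "log"), smoothing_alpha = 0,
                           external_rule = TRUE, include_history = TRUE,
                           fallback_policy = "pooled",
                           nb_alpha = 1, nb_restrict = TRUE, knn_k = 5L,
                           stratify = FALSE,
                           aggregate = c("pooled", "per_fold"),
                           thresholds = c(0.5, 0.7, 0.9, 0.95)) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  aggregate <- match.arg(aggregate)
  unlabeled <- is.na(records$underlying)
  if (any(unlabeled)) {
    stop("cross-validation requires labeled records", call. = FALSE)
  }
  folds <- kfold_split(records, k = k, seed = seed, stratify = stratify)
  fold <- folds$fold
  predicted <- character(nrow(records))
  fold_reports <- vector("list", folds$k)
  for (f in seq_len(folds$k)) {
    test <- fold == f
    train <- records[!test, , drop = FALSE]
    heldout <- records[test, , drop = FALSE]
    preds <- switch(method,
      sink = {
        counts <- accumulate_counts(train, include_history = include_history)
        tbl <- suppressWarnings(
          compute_cdcp(counts, transform = transform,
                       smoothing_alpha = smoothing_alpha))
        sink_infer_batch(heldout, tbl, external_rule = external_rule,
                         include_history = include_history,
                         fallback_policy = fallback_policy)
      },
      nb = naive_bayes_baseline(train, heldout, alpha = nb_alpha,
                                restrict = nb_restrict),
      knn = knn_baseline(train, heldout, k_neighbors = knn_k))
    predicted[test] <- preds$predicted
    if (aggregate == "per_fold") {
      fold_reports[[f]] <- classification_report(heldout$underlying,
                                                 preds$predicted,
                                                 thresholds = thresholds)
    }
  }
  report <- classification_report(records$underlying, predicted,
                                  thresholds = thresholds)
  report$method <- method
  report$k <- folds$k
  report$seed <- folds$seed
  report$predictions <- data.frame(record_id = records$record_id,
                                   truth = records$underlying,
                                   predicted = predicted, fold = unname(fold),
                                   stringsAsFactors = FALSE)
  if (aggregate == "per_fold") {
    report$per_fold <- list(
      macro_f1 = mean(vapply(fold_reports, `[[`, 0, "macro_f1")),
      macro_precision = mean(vapply(fold_reports, `[[`, 0, "macro_precision")),
      macro_recall = mean(vapply(fold_reports, `[[`, 0, "macro_recall")),
      micro_f1 = mean(vapply(fold_reports, `[[`, 0, "micro_f1")))
  }
  report
}

record_feature_matrix <- function(records, vocab) {
  n <- nrow(records)
  cm <- record_chain_matrix(records)
  idx <- rep(seq_len(n), times = ncol(cm))
  code <- as.vector(cm)
  keep <- !is.na(code) & nzchar(code)
  idx <- idx[keep]; code <- code[keep]
  hl <- record_history_list(records)
  idx <- c(idx, rep(seq_len(n), times = lengths(hl)))
  code <- c(code, unlist(hl, use.names = FALSE))
  j <- match(code, vocab)
  keep <- !is.na(j)
  m <- matrix(0, n, length(vocab), dimnames = list(NULL, vocab))
  m[cbind(idx[keep], j[keep])] <- 1
  m
}

record_candidates <- function(records) {
  hl <- record_history_list(records)
  cm <- record_chain_matrix(records)
  lapply(seq_len(nrow(records)), function(i) {
    ch <- cm[i, ]
    unique(c(ch[!is.na(ch) & nzchar(ch)], hl[[i]]))
  })
}

#' Naive Bayes reference baseline
#'
#' Bernoulli naive Bayes over the presence of each cause code on the record
#' (chain and history), plus categorical age-group and gender features, with
#' additive smoothing. Classes are the underlying causes observed in
#' training. By default the argmax is restricted to the record's candidate
#' set (chain plus history), matching the problem's constraint that the
#' underlying cause appears on the record; `restrict = FALSE` gives the
#' unrestricted variant. Ties go to the lexicographically smallest class.
#'
#' @param train labeled `death_records`.
#' @param test `death_records` to predict.
#' @param alpha additive smoothing (> 0 recommended).
#' @param restrict restrict predictions to the candidate set.
#' @return data frame `record_id, predicted, score, source, tie_broken`
#'   where `score` is the winning unnormalized log-posterior.
#' @export
naive_bayes_baseline <- function(train, test, alpha = 1, restrict = TRUE) {
  if (nrow(train) == 0L) stop("empty training set", call. = FALSE)
  stopifnot(alpha >= 0)
  classes <- sort(unique(train$underlying), method = "radix")
  vocab <- sort(unique(c(as.vector(record_chain_matrix(train)),
                         unlist(record_history_list(train)))),
                method = "radix")
  vocab <- vocab[!is.na(vocab) & nzchar(vocab)]
  m_tr <- record_feature_matrix(train, vocab)
  cls <- factor(train$underlying, levels = classes)
  n_u <- as.numeric(table(cls))
  c1 <- rowsum(m_tr, cls)                       # classes x vocab
  logp1 <- log((c1 + alpha) / (n_u + 2 * alpha))
  logp0 <- log((n_u - c1 + alpha) / (n_u + 2 * alpha))
  ag_tr <- age_group(train$age)
  c_ag <- table(cls, ag_tr)                     # classes x 3
  logp_ag <- log(sweep(c_ag + alpha, 1, n_u + 3 * alpha, "/"))
  g_tr <- factor(train$sex, levels = gender_levels())
  c_g <- table(cls, g_tr)
  logp_g <- log(sweep(c_g + alpha, 1, n_u + 2 * alpha, "/"))
  log_prior <- log((n_u + alpha) / (nrow(train) + alpha * length(classes)))

  m_te <- record_feature_matrix(test, vocab)
  scores <- m_te %*% t(logp1 - logp0)
  scores <- sweep(scores, 2, rowSums(logp0) + log_prior, "+")
  ag_te <- as.integer(age_group(test$age))
  g_te <- match(test$sex, gender_levels())
  scores <- scores + t(logp_ag)[ag_te, , drop = FALSE] +
    t(logp_g)[g_te, , drop = FALSE]

  cand <- record_candidates(test)
  n_te <- nrow(test)
  predicted <- character(n_te)
  best <- numeric(n_te)
  tie <- logical(n_te)
  for (i in seq_len(n_te)) {
    allowed <- seq_along(classes)
    if (restrict) {
      a <- which(classes %in% cand[[i]])
      if (length(a)) allowed <- a
    }
    s <- scores[i, allowed]
    w <- which.max(s)                            # first max = smallest class
    predicted[i] <- classes[allowed[w]]
    best[i] <- s[w]
    tie[i] <- sum(s == s[w]) > 1L
  }
  data.frame(record_id = test$record_id, predicted = predicted, score = best,
             source = "nb", tie_broken = tie, stringsAsFactors = FALSE)
}

#' K-nearest-neighbour reference baseline
#'
#' Hamming distance on the multi-hot cause vector (chain plus history) plus
#' age-group and gender mismatch indicators. The prediction is the majority
#' underlying label among the `k_neighbors` nearest training records;
#' neighbour ranking and label ties are broken deterministically (distance,
#' then label, then record id; label ties by smallest distance sum, then
#' lexicographic label), so predictions are invariant to the order of the
#' training set.
#'
#' @param train labeled `death_records`.
#' @param test `death_records` to predict.
#' @param k_neighbors neighbourhood size (>= 1, <= nrow(train)).
#' @return data frame `record_id, predicted, score, source, tie_broken`
#'   where `score` is the mean distance of the selected neighbours.
#' @export
knn_baseline <- function(train, test, k_neighbors = 5L) {
  k_neighbors <- as.integer(k_neighbors)
  if (nrow(train) == 0L) stop("empty training set", call. = FALSE)
  if (k_neighbors < 1L || k_neighbors > nrow(train)) {
    stop("k_neighbors must be in [1, nrow(train)]", call. = FALSE)
  }
  vocab <- sort(unique(c(as.vector(record_chain_matrix(train)),
                         unlist(record_history_list(train)),
                         as.vector(record_chain_matrix(test)),
                         unlist(record_history_list(test)))),
                method = "radix")
  vocab <- vocab[!is.na(vocab) & nzchar(vocab)]
  x_tr <- record_feature_matrix(train, vocab)
  x_te <- record_feature_matrix(test, vocab)
  # Hamming distance on binary vectors: |x| + |y| - 2 x.y
  d <- outer(rowSums(x_te), rowSums(x_tr), "+") - 2 * tcrossprod(x_te, x_tr)
  d <- d + outer(as.character(age_group(test$age)),
                 as.character(age_group(train$age)), "!=")
  d <- d + outer(test$sex, train$sex, "!=")
  lab <- train$underlying
  ord_lab <- xtfrm(lab)
  ord_id <- xtfrm(train$record_id)
  n_te <- nrow(test)
  predicted <- character(n_te)
  meand <- numeric(n_te)
  tie <- logical(n_te)
  for (i in seq_len(n_te)) {
    di <- d[i, ]
    o <- order(di, ord_lab, ord_id, method = "radix")[seq_len(k_neighbors)]
    votes <- table(lab[o])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      sums <- vapply(top, function(u) sum(di[o][lab[o] == u]), 0)
      top <- top[sums == min(sums)]
      top <- sort(top, method = "radix")
      tie[i] <- TRUE
    }
    predicted[i] <- top[1L]
    meand[i] <- mean(di[o])
  }
  data.frame(record_id = test$record_id, predicted = predicted,
             score = meand, source = "knn", tie_broken = tie,
             stringsAsFactors = FALSE)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation report (n = %d%s)\n", x$n,
              if (!is.null(x$method)) paste0(", method = ", x$method,
                                             ", k = ", x$k) else ""))
  cat(sprintf("  macro P/R/F1: %.4f / %.4f / %.4f\n",
              x$macro_precision, x$macro_recall, x$macro_f1))
  cat(sprintf("  micro (accuracy): %.4f\n", x$micro_f1))
  cat("  fraction of causes with F1 above threshold:\n")
  print(round(x$f1_fraction_above, 4))
  invisible(x)
}
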