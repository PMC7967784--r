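test_that("kfold_split partitions records with balanced folds", {
  coh <- generate_cohort(small_config(n = 170L, seed = 1L))
  # pigeonhole: 17 records into 17 folds
  f <- kfold_split(coh[1:17, ], k = 17, seed = 3)
  expect_equal(sort(unname(f$fold)), 1:17)
  # balanced sizes, disjoint and exhaustive
  for (k in c(2, 5, 17)) {
    f <- kfold_split(coh, k = k, seed = 3)
    expect_equal(length(f$fold), 170L)
    expect_setequal(names(f$fold), coh$record_id)
    sizes <- tabulate(f$fold, k)
    expect_true(max(sizes) - min(sizes) <= 1L)
  }
  # seeded determinism
  expect_identical(kfold_split(coh, 17, seed = 5), kfold_split(coh, 17, seed = 5))
  expect_false(identical(kfold_split(coh, 17, seed = 5)$fold,
                         kfold_split(coh, 17, seed = 6)$fold))
  expect_error(kfold_split(coh[1:10, ], k = 11), "exceeds")
  expect_error(kfold_split(coh, k = 1), "at least 2")
})

test_that("a 50,000-record cohort splits 17 ways into folds of 2941 or 2942", {
  ids <- data.frame(record_id = sprintf("r%05d", 1:50000),
                    underlying = "I25.1", stringsAsFactors = FALSE)
  f <- kfold_split(ids, k = 17, seed = 9)
  sizes <- sort(unique(tabulate(f$fold, 17)))
  expect_equal(sizes, c(2941L, 2942L))
  expect_equal(sum(tabulate(f$fold, 17)), 50000L)
})

test_that("stratified folds spread rare causes while staying balanced", {
  coh <- generate_cohort(small_config(n = 340L, seed = 2L))
  f <- kfold_split(coh, k = 17, seed = 4, stratify = TRUE)
  sizes <- tabulate(f$fold, 17)
  expect_true(max(sizes) - min(sizes) <= 1L)
  # any cause with >= 17 labeled deaths appears in every fold
  tab <- table(coh$underlying)
  common <- names(tab)[tab >= 17]
  for (u in common) {
    folds_hit <- unique(f$fold[coh$record_id[coh$underlying == u]])
    expect_equal(length(folds_hit), 17L)
  }
})

test_that("classification metrics match a hand-computed confusion matrix", {
  # cause X: tp=2, fp=1, fn=0 -> precision 2/3, recall 1, F1 0.8
  truth <- c("X", "X", "Y", "Y", "Y", "Y")
  pred <- c("X", "X", "X", "Y", "Y", "Y")
  rep <- classification_report(truth, pred)
  px <- rep$per_cause[rep$per_cause$cause == "X", ]
  expect_equal(px$precision, 2 / 3)
  expect_equal(px$recall, 1)
  expect_equal(px$f1, 0.8)
  expect_equal(px$support, 2L)
  py <- rep$per_cause[rep$per_cause$cause == "Y", ]
  expect_equal(py$precision, 1)
  expect_equal(py$recall, 3 / 4)
  expect_equal(rep$micro_f1, 5 / 6)
  # perfect predictions: every metric 1
  perf <- classification_report(truth, truth)
  expect_true(all(perf$per_cause$f1 == 1))
  expect_equal(perf$macro_f1, 1)
  expect_equal(unname(perf$f1_fraction_above["0.95"]), 1)
})

test_that("micro precision = recall = F1 in the single-label setting", {
  for (seed in 1:5) {
    coh <- generate_cohort(small_config(n = 200L, seed = seed))
    tbl <- compute_cdcp(accumulate_counts(coh))
    pred <- sink_infer_batch(coh, tbl)$predicted
    rep <- classification_report(coh$underlying, pred)
    expect_identical(rep$micro_precision, rep$micro_recall)
    expect_identical(rep$micro_recall, rep$micro_f1)
    expect_true(all(rep$per_cause$f1 >= 0 & rep$per_cause$f1 <= 1))
  }
})

test_that("f1_distribution counts threshold exceedances and is non-increasing", {
  rep <- classification_report(c("A", "B", "C", "D"), c("A", "B", "C", "D"))
  rep$per_cause$f1 <- c(1.0, 0.9, 0.5, 0.2)
  expect_equal(unname(f1_distribution(rep, 0.7)), 0.5)
  fr <- f1_distribution(rep, c(0.1, 0.4, 0.7, 0.95))
  expect_true(all(diff(fr) <= 0))
  rep$per_cause <- rep$per_cause[0, ]
  expect_error(f1_distribution(rep), "no per-cause")
})

test_that("cross-validation partitions the data and pools held-out predictions", {
  coh <- generate_cohort(small_config(n = 340L, seed = 8L))
  rep <- cross_validate(coh, k = 17, seed = 2)
  expect_equal(rep$n, 340L)
  expect_setequal(rep$predictions$record_id, coh$record_id)
  expect_equal(sort(unique(rep$predictions$fold)), 1:17)
  expect_true(rep$macro_f1 >= 0 && rep$macro_f1 <= 1)
  # fixed seed -> identical report
  expect_identical(rep, cross_validate(coh, k = 17, seed = 2))
  # per-fold aggregate variant
  repf <- cross_validate(coh, k = 5, seed = 2, aggregate = "per_fold")
  expect_true(is.numeric(repf$per_fold$macro_f1))
})

test_that("naive Bayes matches a manual posterior computation", {
  # two classes; presence features; alpha = 1
  train <- make_records(list(
    list(chain = c("X10.0", "A10.0"), underlying = "X10.0", age = 70),
    list(chain = c("X10.0", "A10.0"), underlying = "X10.0", age = 70),
    list(chain = c("X10.0", "B10.0"), underlying = "X10.0", age = 70),
    list(chain = c("A10.0", "B10.0"), underlying = "A10.0", age = 70),
    list(chain = c("A10.0", "B10.0"), underlying = "A10.0", age = 70),
    list(chain = c("A10.0"), underlying = "A10.0", age = 70)))
  test <- make_records(list(list(chain = c("X10.0", "A10.0"), age = 70)))
  res <- naive_bayes_baseline(train, test, alpha = 1)
  # manual Bayes: classes X10.0 (n=3) and A10.0 (n=3); vocab {A10.0,B10.0,X10.0}
  # P(X10.0 present | X)=(3+1)/5, (A present|X)=(2+1)/5, (B absent... ) etc.
  lx <- log(4 / 8) + log(4 / 5) + log(3 / 5) + log((5 - 2) / 5)   # class X10.0
  la <- log(4 / 8) + log(1 / 5) + log(4 / 5) + log((5 - 3) / 5)   # class A10.0
  # both candidates allowed; X10.0 has the larger posterior
  expect_true(lx > la)
  expect_equal(res$predicted, "X10.0")
  # degenerate posterior: a cause always underlying when present
  always <- make_records(list(
    list(chain = c("C10.1", "A10.0"), underlying = "C10.1"),
    list(chain = c("C10.1", "B10.0"), underlying = "C10.1"),
    list(chain = c("A10.0", "B10.0"), underlying = "B10.0")))
  t2 <- make_records(list(list(chain = c("C10.1", "A10.0"))))
  expect_equal(naive_bayes_baseline(always, t2)$predicted, "C10.1")
  # deterministic across repeat runs
  expect_identical(naive_bayes_baseline(train, test),
                   naive_bayes_baseline(train, test))
  expect_error(naive_bayes_baseline(train[0, ], test), "empty")
})

test_that("KNN matches exhaustive distance enumeration on a tiny fixture", {
  train <- make_records(list(
    list(record_id = "a", chain = c("A10.0", "B10.0"), underlying = "A10.0",
         age = 70, sex = "male"),
    list(record_id = "b", chain = c("A10.0", "B10.0"), underlying = "B10.0",
         age = 70, sex = "male"),
    list(record_id = "c", chain = c("A10.0"), underlying = "A10.0",
         age = 70, sex = "male"),
    list(record_id = "d", chain = c("C10.1"), underlying = "C10.1",
         age = 10, sex = "female"),
    list(record_id = "e", chain = c("C10.1", "B10.0"), underlying = "C10.1",
         age = 10, sex = "female")))
  # test record: chain {A10.0,B10.0}, old male
  # distances: a=0, b=0, c=1, d=5, e=4 -> k=3 neighbourhood {a,b,c}
  # votes: A10.0 x2 (a,c), B10.0 x1 -> A10.0
  test <- make_records(list(list(chain = c("A10.0", "B10.0"), age = 70,
                                 sex = "male")))
  res <- knn_baseline(train, test, k_neighbors = 3)
  expect_equal(res$predicted, "A10.0")
  # zero-distance identical record with k=1 returns its label
  expect_equal(knn_baseline(train, test, k_neighbors = 1)$predicted, "A10.0")
  expect_error(knn_baseline(train, test, k_neighbors = 9), "k_neighbors")
  # training order invariance
  perm <- c(4, 2, 5, 1, 3)
  expect_equal(knn_baseline(train[perm, ], test, k_neighbors = 3)$predicted,
               res$predicted)
})

test_that("baselines plug into cross-validation", {
  coh <- generate_cohort(small_config(n = 200L, seed = 12L))
  for (m in c("nb", "knn")) {
    rep <- cross_validate(coh, k = 4, seed = 3, method = m)
    expect_equal(rep$method, m)
    expect_true(rep$macro_f1 >= 0 && rep$macro_f1 <= 1)
  }
})
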