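test_that("stratified split preserves the acquisition-layout arithmetic", {
  fm <- blob_features(40, 3, seed = 1)
  # emulate the real per-class sizes with a light-weight label table
  labels <- tibble::tibble(class_index = rep(c(0L, 1L, 2L), c(9600L, 1200L, 1200L)))
  sp <- stratified_split(labels, 0.2, seed = 2)
  expect_equal(sum(sp$holdout$class_index == 0), 1920L)
  expect_equal(sum(sp$holdout$class_index == 1), 240L)
  expect_equal(sum(sp$train$class_index == 1), 960L)
  expect_equal(nrow(sp$train) + nrow(sp$holdout), nrow(labels))
  # disjoint and exhaustive on real features
  sp2 <- stratified_split(fm, 0.25, seed = 3)
  expect_length(intersect(sp2$train$spectrum_id, sp2$holdout$spectrum_id), 0)
  expect_setequal(c(sp2$train$spectrum_id, sp2$holdout$spectrum_id),
                  fm$spectrum_id)
  expect_equal(nrow(stratified_split(fm, 0)$holdout), 0L)
  tiny <- tibble::tibble(class_index = c(0L, 0L, 1L, 1L, 1L, 1L, 1L))
  expect_error(stratified_split(tiny, 0.2), "at least 5")
})

test_that("classifier metrics match hand arithmetic on random confusion tables", {
  withr::with_seed(10, {
    for (rep in 1:100) {
      k <- sample(2:6, 1)
      cm <- matrix(rpois(k * k, 8), k, k,
                   dimnames = list(true = 1:k, predicted = 1:k))
      got <- confusion_metrics(cm)
      n <- sum(cm)
      for (i in seq_len(k)) {
        tp <- cm[i, i]
        fn <- sum(cm[i, ]) - tp
        fp <- sum(cm[, i]) - tp
        tn <- n - tp - fn - fp
        expect_equal(got$sensitivity[i], tp / (tp + fn))
        expect_equal(got$specificity[i], tn / (tn + fp))
        expect_equal(got$accuracy[i], (tp + tn) / n)
      }
    }
  })
  hand <- confusion_metrics(matrix(c(8, 1, 2, 9), 2,
                                   dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(hand$sensitivity[1], 0.8)
  expect_equal(hand$specificity[1], 0.9)
  expect_equal(hand$accuracy[1], 0.85)
})

test_that("SVM separates clean clusters and is deterministic", {
  fm <- blob_features(30, 4, sep = 10, seed = 4)
  clf <- train_svm(fm)
  expect_equal(mean(predict(clf, fm) == fm$class_index), 1)
  clf2 <- train_svm(fm)
  ev1 <- evaluate_classifier(clf, fm)
  ev2 <- evaluate_classifier(clf2, fm)
  expect_identical(ev1$confusion, ev2$confusion)
  expect_error(train_svm(fm[fm$class_index == 0, ]), "2 classes")
})

test_that("evaluation rejects unseen classes and scores the degenerate predictor", {
  fm <- blob_features(30, 2, sep = 10, seed = 5)
  clf <- train_svm(fm)
  other <- blob_features(30, 3, sep = 10, seed = 5)
  expect_error(evaluate_classifier(clf, other), "never seen")
  # an all-one-class predictor on balanced two-class data
  cm <- matrix(c(15L, 15L, 0L, 0L), 2, 2,
               dimnames = list(c("0", "1"), c("0", "1")))
  m <- confusion_metrics(cm)
  expect_equal(m$sensitivity[1], 1)
  expect_equal(m$specificity[1], 0)
  expect_error(evaluate_classifier(clf, fm[0, ]), "empty")
})

test_that("cross-validation folds partition the data and keep SMOTE out of validation", {
  fm <- blob_features(30, 3, sep = 8, seed = 6)
  cv <- crossvalidate(fm, n_folds = 5, seed = 7)
  expect_equal(nrow(cv), 5L)
  ids <- sort(unlist(cv$val_ids))
  expect_equal(ids, sort(fm$spectrum_id))          # partition, no overlap
  expect_false(any(grepl("^smote_", ids)))          # leakage audit
  expect_true(all(cv$accuracy >= 0 & cv$accuracy <= 1))
  expect_error(crossvalidate(fm, n_folds = 40), "n_folds")
})

test_that("the classification LOD rule matches a brute-force reading", {
  conc <- 10^(-12:-9)
  lev <- c("0", "1", "2", "3", "4")
  perfect <- diag(5) * 100
  dimnames(perfect) <- list(lev, lev)
  lod <- determine_lod_classification(perfect, conc)
  expect_equal(lod$lod, conc[1])
  # class 1 confuses 5% with control; classes 2+ are clean
  cm <- diag(c(100, 95, 100, 100, 100))
  cm[2, 1] <- 5
  dimnames(cm) <- list(lev, lev)
  lod2 <- determine_lod_classification(cm, conc)
  expect_equal(lod2$lod_class, 2L)
  expect_equal(lod2$lod, conc[2])
  # everything predicted control: not detected
  allc <- matrix(0, 5, 5, dimnames = list(lev, lev))
  allc[, 1] <- 100
  lod3 <- determine_lod_classification(allc, conc)
  expect_false(lod3$detected)
  expect_true(is.na(lod3$lod))
})

test_that("the LOD rule agrees with an independent loop oracle and is monotone", {
  oracle <- function(cm, conc, thr = 0.02) {
    lev <- rownames(cm)
    nz <- lev[lev != "0"]
    best <- NA_real_
    for (i in seq_along(nz)) {
      ok <- TRUE
      for (j in i:length(nz)) {
        fc <- cm[nz[j], "0"] / sum(cm[nz[j], ])
        cf <- cm["0", nz[j]] / sum(cm["0", ])
        if (!(fc < thr && cf < thr)) ok <- FALSE
      }
      if (ok) { best <- conc[i]; break }
    }
    best
  }
  withr::with_seed(12, {
    conc <- 10^(-13:-10)
    lev <- as.character(0:4)
    for (rep in 1:25) {
      cm <- matrix(rpois(25, 3), 5, 5, dimnames = list(lev, lev))
      diag(cm) <- diag(cm) + sample(50:300, 5)
      got <- determine_lod_classification(cm, conc)
      want <- oracle(cm, conc)
      expect_equal(got$lod, want)
      # adding control confusion at or above the LOD can only raise/void it
      if (got$detected) {
        worse <- cm
        worse[got$lod_class + 1L, 1L] <- worse[got$lod_class + 1L, 1L] + 1000L
        got2 <- determine_lod_classification(worse, conc)
        expect_true(!got2$detected || got2$lod > got$lod)
      }
    }
  })
})
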