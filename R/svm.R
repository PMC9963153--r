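#' Stratified train/holdout split
#'
#' Splits rows by class with per-class proportions preserved to within one
#' sample (`round(n_c * holdout_frac)` holdout rows per class), disjoint and
#' exhaustive. With the acquisition layout of 1,200 spectra per exposed
#' class and 9,600 controls, a 20% holdout yields 240 and 1,920 rows.
#'
#' @param fm A `sers_features` tibble (any tibble with a `class_index`
#'   column works).
#' @param holdout_frac Fraction held out (default 0.2).
#' @param seed Optional seed.
#' @return List with `train` and `holdout`.
#' @export
stratified_split <- function(fm, holdout_frac = 0.2, seed = NULL) {
  if (holdout_frac < 0 || holdout_frac >= 1) abort("`holdout_frac` must be in [0, 1).")
  counts <- table(fm$class_index)
  if (holdout_frac > 0 && any(counts < 5L)) {
    abort("Every class needs at least 5 samples for a stratified split.")
  }
  with_seed(seed, {
    hold <- integer(0)
    for (cls in names(counts)) {
      idx <- which(fm$class_index == as.integer(cls))
      n_h <- round(length(idx) * holdout_frac)
      if (n_h > 0L) hold <- c(hold, sample(idx, n_h))
    }
    hold <- sort(hold)
    list(train = fm[setdiff(seq_len(nrow(fm)), hold), ],
         holdout = fm[hold, ])
  })
}

#' SVM configuration
#'
#' Radial-basis-function kernel with margin parameter `C = 1` and
#' `gamma = "scale"`, i.e. `1 / (n_features * Var(scores))` with the
#' population variance of the whole score matrix.
#'
#' @param C Margin parameter (> 0).
#' @param gamma `"scale"` or a positive number.
#' @param seed Integer seed.
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(C = 1, gamma = "scale", seed = 1L) {
  assert_scalar_number(C, "C", min = 0, strict = TRUE)
  structure(list(kernel = "radial", C = C, gamma = gamma, seed = as.integer(seed)),
            class = "svm_config")
}

#' Train an SVM concentration (or metal-type) classifier
#'
#' Fits a multiclass RBF support-vector machine on the PCA scores with class
#' labels `class_index`. Deterministic given the data.
#'
#' @param train A `sers_features` tibble with >= 2 classes.
#' @param cfg An [svm_config()].
#' @param label Column holding the class label (default `class_index`).
#' @return An object of class `sers_svm`.
#' @export
train_svm <- function(train, cfg = svm_config(), label = "class_index") {
  S <- score_matrix(train)
  y <- train[[label]]
  classes <- sort(unique(y))
  if (length(classes) < 2L) abort("Training data must contain at least 2 classes.")
  g <- if (identical(cfg$gamma, "scale")) {
    v <- mean((S - mean(S))^2)
    1 / (ncol(S) * v)
  } else cfg$gamma
  fit <- with_seed(cfg$seed,
    e1071::svm(x = S, y = factor(y, levels = classes), kernel = "radial",
               cost = cfg$C, gamma = g, scale = FALSE))
  structure(list(model = fit, classes = classes, gamma = g, config = cfg,
                 label = label),
            class = "sers_svm")
}

#' @export
predict.sers_svm <- function(object, newdata, ...) {
  S <- if (is.matrix(newdata)) newdata else score_matrix(newdata)
  pred <- predict(object$model, S)
  cls <- object$classes
  cls[match(as.character(pred), as.character(cls))]
}

#' Confusion matrix and one-vs-rest metrics on a holdout set
#'
#' Rows are true classes, columns predicted, ordered control first then
#' ascending class index. Per class `c` (one-vs-rest):
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/n`.
#'
#' @param clf A [train_svm()] model (or any object with a `predict` method
#'   returning class labels).
#' @param holdout Nonempty `sers_features` tibble.
#' @return An object of class `sers_eval` with elements `confusion`
#'   (integer matrix), `metrics` (tibble) and `accuracy` (overall).
#' @export
evaluate_classifier <- function(clf, holdout) {
  if (nrow(holdout) == 0L) abort("Holdout set is empty.")
  truth <- holdout[[clf$label %||% "class_index"]]
  unseen <- setdiff(unique(truth), clf$classes)
  if (length(unseen)) {
    abort(sprintf("Holdout contains classes never seen in training: %s",
                  paste(unseen, collapse = ", ")))
  }
  pred <- predict(clf, holdout)
  lev <- clf$classes
  cm <- table(factor(truth, levels = lev), factor(pred, levels = lev))
  cm <- matrix(as.integer(cm), nrow = length(lev),
               dimnames = list(true = lev, predicted = lev))
  new_sers_eval(cm)
}

new_sers_eval <- function(cm) {
  structure(list(confusion = cm, metrics = confusion_metrics(cm),
                 accuracy = sum(diag(cm)) / sum(cm)),
            class = "sers_eval")
}

#' One-vs-rest metrics of a confusion matrix
#'
#' @param cm Square counts matrix, rows = true classes.
#' @return Tibble with per-class sensitivity, specificity and accuracy.
#' @export
confusion_metrics <- function(cm) {
  n <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- n - tp - fn - fp
  tibble::tibble(
    class = rownames(cm) %||% as.character(seq_len(nrow(cm))),
    sensitivity = unname(tp / (tp + fn)),
    specificity = unname(tn / (tn + fp)),
    accuracy = unname((tp + tn) / n)
  )
}

#' Leakage-safe stratified cross-validation
#'
#' Stratified `n_folds`-fold cross-validation in which SMOTE balancing is
#' applied *inside* each training fold only, after the fold split, so no
#' synthetic row can reach a validation fold.
#'
#' @param fm A `sers_features` tibble; every class must have at least
#'   `n_folds` rows.
#' @param cfg An [svm_config()].
#' @param n_folds Number of folds (default 10).
#' @param smote_k SMOTE neighbourhood size.
#' @param seed Optional seed.
#' @return Tibble with one row per fold: overall accuracy, macro-averaged
#'   sensitivity/specificity, validation size and the validation row ids
#'   (list-column, for leakage audits).
#' @export
crossvalidate <- function(fm, cfg = svm_config(), n_folds = 10L, smote_k = 5L,
                          seed = NULL) {
  counts <- table(fm$class_index)
  if (any(counts < n_folds)) abort("Every class needs >= n_folds samples.")
  with_seed(seed, {
    fold_of <- integer(nrow(fm))
    for (cls in names(counts)) {
      idx <- sample(which(fm$class_index == as.integer(cls)))
      fold_of[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    out <- vector("list", n_folds)
    for (f in seq_len(n_folds)) {
      tr <- fm[fold_of != f, ]
      va <- fm[fold_of == f, ]
      tr <- smote_oversample(tr, k = smote_k)
      clf <- train_svm(tr, cfg)
      ev <- evaluate_classifier(clf, va)
      out[[f]] <- tibble::tibble(
        fold = f, n_val = nrow(va), accuracy = ev$accuracy,
        macro_sensitivity = mean(ev$metrics$sensitivity, na.rm = TRUE),
        macro_specificity = mean(ev$metrics$specificity, na.rm = TRUE),
        val_ids = list(va$spectrum_id)
      )
    }
    dplyr::bind_rows(out)
  })
}

#' Classification-based limit of detection
#'
#' Operationalizes the "better than 98% distinguished from control" rule
#' symmetrically: a class passes when fewer than `threshold` (default 2%) of
#' its holdout spectra are predicted as control *and* fewer than `threshold`
#' of the control holdout is predicted as that class. The LOD is the
#' smallest concentration whose class and all higher-concentration classes
#' pass, so the rule cannot produce a non-monotone detection limit. The
#' `"row_only"` rule gates only the first direction.
#'
#' @param eval A `sers_eval` (or bare confusion matrix with control row "0").
#' @param concentrations mol/L of the nonzero classes, ascending, matching
#'   the nonzero class indices in order.
#' @param threshold Confusion fraction gate (default 0.02).
#' @param rule `"symmetric"` (default) or `"row_only"`.
#' @return List of class `sers_lod`: `lod` (mol/L, `NA` if not detected),
#'   `lod_class`, `detected`, and per-class confusion fractions.
#' @export
determine_lod_classification <- function(eval, concentrations, threshold = 0.02,
                                         rule = c("symmetric", "row_only")) {
  rule <- match.arg(rule)
  cm <- if (inherits(eval, "sers_eval")) eval$confusion else eval
  lev <- rownames(cm)
  if (!"0" %in% lev) abort("Confusion matrix has no control class (index 0).")
  nz <- lev[lev != "0"]
  nz <- nz[order(as.numeric(nz))]
  if (length(nz) != length(concentrations)) {
    abort("`concentrations` must have one entry per nonzero class.")
  }
  frac_as_control <- cm[nz, "0"] / rowSums(cm[nz, , drop = FALSE])
  frac_control_as <- cm["0", nz] / sum(cm["0", ])
  pass <- if (rule == "symmetric") {
    frac_as_control < threshold & frac_control_as < threshold
  } else {
    frac_as_control < threshold
  }
  ok_from <- rev(cumprod(rev(pass))) > 0  # pass holds for this and all larger
  per_class <- tibble::tibble(
    class = as.integer(nz), concentration_molar = concentrations,
    frac_predicted_control = as.numeric(frac_as_control),
    frac_control_predicted_as = as.numeric(frac_control_as),
    pass = pass
  )
  i <- which(ok_from)[1]
  structure(list(
    detected = !is.na(i),
    lod = if (!is.na(i)) concentrations[i] else NA_real_,
    lod_class = if (!is.na(i)) as.integer(nz[i]) else NA_integer_,
    per_class = per_class, threshold = threshold, rule = rule
  ), class = "sers_lod")
}
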