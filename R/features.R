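#' Fit a PCA basis on a spectral dataset
#'
#' Mean-centred principal axes of the intensity matrix, ordered by
#' descending explained variance, truncated to `n_components` (default 22,
#' the dimensionality used throughout the classification and regression
#' models). Component signs follow the convention that each loading's
#' largest-magnitude entry is positive, which makes bases comparable across
#' fits.
#'
#' @param ds A `sers_dataset` with more spectra than components.
#' @param n_components Number of components to retain.
#' @return An object of class `sers_pca`: `mean_spectrum`, `components`
#'   (p x k orthonormal loadings), `explained_variance_ratio` (length k) and
#'   the training grid.
#' @export
fit_pca <- function(ds, n_components = 22L) {
  X <- intensity_matrix(ds)
  if (nrow(X) <= n_components) {
    abort(sprintf("Need more than %d spectra to fit %d components.",
                  n_components, n_components))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(mean_spectrum = pc$center, components = rot,
                 explained_variance_ratio = evr[seq_len(k)],
                 n_components = k, wavenumbers = wavenumbers(ds)),
            class = "sers_pca")
}

#' Project spectra onto a fitted PCA basis
#'
#' `scores = (x - mean) %*% components`. The dataset grid must match the
#' basis grid exactly.
#'
#' @param ds A `sers_dataset`.
#' @param basis A [fit_pca()] result.
#' @return A tibble of class `sers_features`: metadata columns, a
#'   `synthetic` flag (FALSE for measured spectra) and score columns
#'   `PC1..PCk`; the basis travels along as the `basis` attribute.
#' @export
project_pca <- function(ds, basis) {
  if (!inherits(basis, "sers_pca")) abort("`basis` must be a `sers_pca`.")
  wn <- wavenumbers(ds)
  if (length(wn) != length(basis$wavenumbers) ||
      any(abs(wn - basis$wavenumbers) > 1e-8)) {
    abort("Dataset grid does not match the PCA basis grid.")
  }
  X <- intensity_matrix(ds)
  scores <- sweep(X, 2, basis$mean_spectrum) %*% basis$components
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  meta <- tibble::as_tibble(ds)[, c("spectrum_id", "metal", "concentration_molar",
                                    "class_index", "surface_id", "replicate_id",
                                    "map_id", "water_matrix")]
  meta$synthetic <- FALSE
  out <- dplyr::bind_cols(meta, tibble::as_tibble(scores))
  new_sers_features(out, basis)
}

new_sers_features <- function(df, basis) {
  structure(df, basis = basis,
            class = c("sers_features", class(tibble::tibble())))
}

#' @export
`[.sers_features` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "basis") <- attr(x, "basis")
    class(out) <- class(x)
  }
  out
}

#' @rdname project_pca
#' @param fm A `sers_features` tibble.
#' @export
score_matrix <- function(fm) {
  as.matrix(tibble::as_tibble(fm)[, grep("^PC[0-9]+$", names(fm), value = TRUE)])
}

#' Reconstruct spectra from leading PCA scores
#'
#' Used to audit how reconstruction error falls as components are added.
#'
#' @param fm A `sers_features` tibble carrying its basis.
#' @param n_components How many leading components to use.
#' @return Reconstructed intensity matrix.
#' @export
reconstruct_pca <- function(fm, n_components = NULL) {
  basis <- attr(fm, "basis")
  S <- score_matrix(fm)
  k <- n_components %||% ncol(S)
  R <- S[, seq_len(k), drop = FALSE] %*% t(basis$components[, seq_len(k), drop = FALSE])
  sweep(R, 2, basis$mean_spectrum, `+`)
}

#' SMOTE oversampling in PCA score space
#'
#' Classic SMOTE: a synthetic row is `x + u * (x_nn - x)` with
#' `u ~ Uniform(0, 1)` and `x_nn` one of the `k` nearest same-class
#' neighbours (Euclidean distance in score space) of a randomly chosen
#' parent. Only call this on training partitions: oversampling before a
#' split leaks synthetic copies of training points into the holdout.
#' Synthetic rows carry `synthetic = TRUE`.
#'
#' @param fm A `sers_features` tibble.
#' @param target_counts Named vector mapping class_index to the desired
#'   count, or `NULL` to balance every class up to the largest.
#' @param k Number of nearest neighbours (default 5).
#' @param seed Optional seed.
#' @return A `sers_features` tibble with appended synthetic rows.
#' @export
smote_oversample <- function(fm, target_counts = NULL, k = 5L, seed = NULL) {
  if (is.null(fm$synthetic)) fm$synthetic <- FALSE
  counts <- table(fm$class_index)
  if (is.null(target_counts)) {
    target_counts <- stats::setNames(rep(max(counts), length(counts)), names(counts))
  }
  with_seed(seed, {
    S <- score_matrix(fm)
    pieces <- list(tibble::as_tibble(fm))
    for (cls in names(target_counts)) {
      cur <- if (cls %in% names(counts)) counts[[cls]] else 0L
      tgt <- target_counts[[cls]]
      if (tgt < cur) abort(sprintf("Target %d below current count %d for class %s.", tgt, cur, cls))
      n_new <- tgt - cur
      if (n_new == 0L) next
      idx <- which(fm$class_index == as.integer(cls) & !fm$synthetic)
      if (length(idx) < 2L) abort(sprintf("Class %s needs >= 2 real samples for SMOTE.", cls))
      Xc <- S[idx, , drop = FALSE]
      kk <- min(k, length(idx) - 1L)
      d2 <- as.matrix(stats::dist(Xc))^2
      diag(d2) <- Inf
      nn <- t(apply(d2, 1, function(r) order(r)[seq_len(kk)]))
      parents <- sample.int(length(idx), n_new, replace = TRUE)
      picks <- nn[cbind(parents, sample.int(kk, n_new, replace = TRUE))]
      u <- runif(n_new)
      Xnew <- Xc[parents, , drop = FALSE] +
        u * (Xc[picks, , drop = FALSE] - Xc[parents, , drop = FALSE])
      newrows <- tibble::as_tibble(fm)[idx[parents], ]
      newrows[, colnames(Xnew)] <- tibble::as_tibble(Xnew)
      newrows$synthetic <- TRUE
      newrows$spectrum_id <- sprintf("smote_%s_%05d", cls, seq_len(n_new))
      pieces[[length(pieces) + 1L]] <- newrows
    }
    new_sers_features(dplyr::bind_rows(pieces), attr(fm, "basis"))
  })
}

#' Uniform down-sampling of one class
#'
#' Seeded sampling without replacement; used to reduce the control class to
#' the exposed-class holdout size (240) before box-plot statistics.
#'
#' @param fm A `sers_features` tibble.
#' @param class_index Class to thin (default 0, the control).
#' @param n Rows to keep.
#' @param seed Optional seed.
#' @return A `sers_features` tibble.
#' @export
downsample_class <- function(fm, class_index = 0L, n = 240L, seed = NULL) {
  idx <- which(fm$class_index == class_index)
  if (length(idx) < n) abort("Class smaller than the requested size.")
  with_seed(seed, {
    keep <- sort(sample(idx, n))
    out <- tibble::as_tibble(fm)[sort(c(setdiff(seq_len(nrow(fm)), idx), keep)), ]
    new_sers_features(out, attr(fm, "basis"))
  })
}

#' Exact t-SNE embedding of PCA scores
#'
#' A compact exact (O(n^2)) t-distributed stochastic neighbour embedding for
#' diagnostic visualization of score space: perplexity-calibrated Gaussian
#' affinities, Student-t low-dimensional kernel, gradient descent with
#' momentum, adaptive gains and early exaggeration. Diagnostics-only: no
#' quantitative contract beyond reproducibility under a fixed seed.
#'
#' @param fm A `sers_features` tibble (or numeric matrix).
#' @param perplexity Target perplexity; requires `n > 3 * perplexity`.
#' @param n_iter Gradient-descent iterations.
#' @param seed Optional seed.
#' @return Tibble with `tsne1`, `tsne2` and the class labels.
#' @export
tsne_embed <- function(fm, perplexity = 30, n_iter = 300L, seed = NULL) {
  X <- if (is.matrix(fm)) fm else score_matrix(fm)
  n <- nrow(X)
  if (n <= 3 * perplexity) abort("Need n > 3 * perplexity for a t-SNE embedding.")
  D2 <- as.matrix(stats::dist(X))^2
  if (all(D2 < 1e-12)) abort("All rows identical; t-SNE is degenerate.")
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / sw
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  with_seed(seed, {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    dY <- matrix(0, n, 2); gains <- matrix(1, n, 2)
    for (iter in seq_len(n_iter)) {
      ex <- if (iter <= 100) 4 else 1
      sumY <- rowSums(Y^2)
      num <- 1 / (1 + outer(sumY, sumY, `+`) - 2 * Y %*% t(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (ex * P - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      gains <- pmax(0.01, ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8))
      mom <- if (iter <= 20) 0.5 else 0.8
      dY <- mom * dY - 100 * gains * grad
      Y <- scale(Y + dY, center = TRUE, scale = FALSE)
    }
    out <- tibble::tibble(tsne1 = Y[, 1], tsne2 = Y[, 2])
    if (!is.matrix(fm)) out$class_index <- fm$class_index
    out
  })
}
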