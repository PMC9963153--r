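random_dataset <- function(n, p, seed = 1) {
  withr::with_seed(seed, {
    sers_dataset(tibble::tibble(.rows = n), matrix(rnorm(n * p), n, p),
                 seq(400, by = 2, length.out = p))
  })
}

test_that("PCA matches the covariance eigendecomposition oracle", {
  for (s in 1:5) {
    n <- sample(8:20, 1)
    p <- sample(4:10, 1)
    ds <- random_dataset(n, p, seed = s)
    k <- min(p, n - 1) - 1L
    b <- fit_pca(ds, k)
    ev <- eigen(stats::cov(intensity_matrix(ds)), symmetric = TRUE)
    for (j in seq_len(k)) {
      expect_equal(abs(sum(b$components[, j] * ev$vectors[, j])), 1,
                   tolerance = 1e-8)
    }
    expect_equal(b$explained_variance_ratio,
                 (ev$values / sum(ev$values))[seq_len(k)], tolerance = 1e-8)
    # orthonormal loadings, sign convention, non-increasing variance
    expect_equal(crossprod(b$components), diag(k), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_true(all(diff(b$explained_variance_ratio) <= 1e-12))
    expect_true(all(vapply(seq_len(k), function(j) {
      b$components[which.max(abs(b$components[, j])), j] > 0
    }, TRUE)))
  }
})

test_that("collinear spectra put all variance on the first component", {
  t <- seq(0, 1, length.out = 30)
  X <- outer(t, rep(1, 12)) * 3 + 1   # rank-1 around the mean
  ds <- sers_dataset(tibble::tibble(.rows = 30), X,
                     seq(400, by = 2, length.out = 12))
  b <- fit_pca(ds, 3)
  expect_equal(b$explained_variance_ratio[1], 1, tolerance = 1e-9)
})

test_that("the default basis size is the 22 components used by the models", {
  ds <- random_dataset(40, 30, seed = 7)
  expect_equal(fit_pca(ds)$n_components, 22L)
  expect_error(fit_pca(random_dataset(10, 30, seed = 1)), "more than")
})

test_that("projection behaves like an orthonormal change of basis", {
  ds <- random_dataset(25, 10, seed = 3)
  b <- fit_pca(ds, 6)
  wn <- wavenumbers(ds)
  mean_ds <- sers_dataset(tibble::tibble(.rows = 1),
                          matrix(b$mean_spectrum, 1), wn)
  expect_equal(as.numeric(score_matrix(project_pca(mean_ds, b))), rep(0, 6),
               tolerance = 1e-9)
  e1 <- sers_dataset(tibble::tibble(.rows = 1),
                     matrix(b$mean_spectrum + b$components[, 1], 1), wn)
  expect_equal(as.numeric(score_matrix(project_pca(e1, b))),
               c(1, rep(0, 5)), tolerance = 1e-9)
  bad <- random_dataset(4, 9, seed = 2)
  expect_error(project_pca(bad, b), "grid")
  # reconstruction error is non-increasing in the number of components
  fm <- project_pca(ds, b)
  X <- intensity_matrix(ds)
  errs <- vapply(1:6, function(k) {
    sum((X - reconstruct_pca(fm, k))^2)
  }, 1)
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("SMOTE hits exact targets with flagged, collinear synthetic rows", {
  fm <- blob_features(960, 2, seed = 5)
  out <- smote_oversample(fm, c(`0` = 960, `1` = 1000), seed = 9)
  expect_equal(sum(out$synthetic), 40L)
  expect_equal(as.integer(table(out$class_index)), c(960L, 1000L))
  S <- as.matrix(out[, paste0("PC", 1:5)])
  real1 <- S[out$class_index == 1 & !out$synthetic, ]
  syn <- S[out$synthetic, ]
  # every synthetic row lies on a segment between two real class members;
  # one endpoint must be among its nearest real neighbours
  for (i in seq_len(nrow(syn))) {
    d <- sweep(real1, 2, syn[i, ])
    near <- order(sqrt(rowSums(d^2)))[1:10]
    resid <- Inf
    for (ai in near) {
      a <- real1[ai, ]
      w <- syn[i, ] - a
      r <- vapply(seq_len(nrow(real1)), function(j) {
        v <- real1[j, ] - a
        nv2 <- sum(v^2)
        if (nv2 < 1e-24) return(Inf)
        sqrt(sum((w - v * sum(w * v) / nv2)^2))  # stable perpendicular part
      }, 1)
      resid <- min(resid, min(r))
    }
    expect_lt(resid, 1e-9)
    # inside the class bounding box (convex-hull consequence of interpolation)
    expect_true(all(syn[i, ] >= apply(real1, 2, min) - 1e-9))
    expect_true(all(syn[i, ] <= apply(real1, 2, max) + 1e-9))
  }
})

test_that("SMOTE is a no-op at current counts and rejects down-sampling", {
  fm <- blob_features(20, 3, seed = 2)
  out <- smote_oversample(fm, c(`0` = 20, `1` = 20, `2` = 20), seed = 1)
  expect_equal(nrow(out), nrow(fm))
  expect_error(smote_oversample(fm, c(`0` = 10), seed = 1), "below current")
})

test_that("control down-sampling is uniform, seeded and exact", {
  fm <- blob_features(500, 2, seed = 8)
  a <- downsample_class(fm, 0L, 240L, seed = 3)
  b <- downsample_class(fm, 0L, 240L, seed = 3)
  expect_identical(a, b)
  expect_equal(sum(a$class_index == 0), 240L)
  expect_equal(sum(a$class_index == 1), 500L)
  expect_true(all(a$spectrum_id[a$class_index == 0] %in%
                  fm$spectrum_id[fm$class_index == 0]))
  expect_error(downsample_class(fm, 0L, 501L), "smaller")
})

test_that("tSNE separates well-separated clusters and is reproducible", {
  skip_if_not_installed("cluster")
  fm <- blob_features(40, 2, sep = 30, seed = 6)
  for (s in 1:5) {
    emb <- tsne_embed(fm, perplexity = 10, n_iter = 150, seed = s)
    expect_equal(dim(as.matrix(emb[, 1:2])), c(80L, 2L))
    sil <- cluster::silhouette(fm$class_index + 1L,
                               stats::dist(as.matrix(emb[, 1:2])))
    expect_gt(mean(sil[, "sil_width"]), 0)
  }
  expect_identical(tsne_embed(fm, perplexity = 10, n_iter = 50, seed = 1),
                   tsne_embed(fm, perplexity = 10, n_iter = 50, seed = 1))
  expect_error(tsne_embed(fm, perplexity = 40), "perplexity")
  dup <- fm
  dup[, paste0("PC", 1:5)] <- 0
  expect_error(tsne_embed(dup, perplexity = 10), "degenerate")
})
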