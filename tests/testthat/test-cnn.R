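# Gaussian prediction sets with controllable spread, for the limit rules.
gauss_predictions <- function(centers, sd, n = 200, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      class_index = rep(seq_along(centers) - 1L, each = n),
      prediction = rnorm(n * length(centers),
                         rep(centers, each = n), sd)
    )
  })
}

test_that("disjoint point-mass predictions give LOD = LOQ = lowest concentration", {
  conc <- 10^(-12:-9)
  preds <- tibble::tibble(class_index = rep(0:4, each = 25),
                          prediction = rep(c(0, 1, 2, 3, 4), each = 25))
  lim <- determine_limits(preds, conc)
  expect_equal(lim$lod, conc[1])
  expect_equal(lim$loq, conc[1])
  expect_equal(lim$dynamic_range, c(conc[1], conc[4]))
  expect_equal(lim$lob, c(0, 0))
})

test_that("all-control-like predictions are not detected", {
  conc <- 10^(-12:-10)
  preds <- gauss_predictions(c(0, 0, 0, 0), sd = 0.1, seed = 3)
  lim <- determine_limits(preds, conc)
  expect_true(is.na(lim$lod))
  expect_true(is.na(lim$loq))
})

test_that("limit rules equal a brute-force counting oracle on random instances", {
  oracle <- function(preds, conc, alpha = 0.005) {
    cls <- sort(unique(preds$class_index))
    iv <- lapply(cls, function(k) {
      quantile(preds$prediction[preds$class_index == k], c(alpha, 1 - alpha),
               type = 7, names = FALSE)
    })
    names(iv) <- cls
    inside <- function(k, ref) {
      x <- preds$prediction[preds$class_index == k]
      mean(x >= iv[[as.character(ref)]][1] & x <= iv[[as.character(ref)]][2])
    }
    nz <- setdiff(cls, 0L)
    lod <- NA; loq <- NA
    for (i in seq_along(nz)) {
      if (all(vapply(nz[i:length(nz)], function(k) inside(k, 0) < alpha, TRUE))) {
        lod <- conc[i]; break
      }
    }
    lod_ok <- function(k) inside(k, 0) < alpha
    for (i in seq_along(nz)) {
      ok <- TRUE
      for (j in i:length(nz)) {
        k <- nz[j]
        lower <- if (j == 1) 0L else nz[j - 1]
        if (inside(k, lower) >= alpha) ok <- FALSE
        if (j < length(nz) && inside(k, nz[j + 1]) >= alpha) ok <- FALSE
        if (!lod_ok(k)) ok <- FALSE
      }
      if (ok) { loq <- conc[i]; break }
    }
    list(lod = lod, loq = loq)
  }
  withr::with_seed(21, {
    for (rep in 1:12) {
      ncls <- sample(3:6, 1)
      centers <- cumsum(c(0, runif(ncls - 1, 0.2, 3)))
      sd <- runif(1, 0.05, 0.8)
      conc <- 10^seq(-13, by = 1, length.out = ncls - 1)
      preds <- gauss_predictions(centers, sd, n = 150, seed = rep)
      got <- determine_limits(preds, conc)
      want <- oracle(preds, conc)
      expect_identical(is.na(got$lod), is.na(want$lod))
      if (!is.na(want$lod)) expect_equal(got$lod, want$lod)
      expect_identical(is.na(got$loq), is.na(want$loq))
      if (!is.na(want$loq)) expect_equal(got$loq, want$loq)
      if (!is.na(got$lod) && !is.na(got$loq)) expect_gte(got$loq, got$lod)
    }
  })
})

test_that("interval statistics use shared percentile definitions", {
  preds <- gauss_predictions(c(0, 2), sd = 0.3, n = 100, seed = 5)
  lim <- determine_limits(preds, 1e-12)
  x0 <- preds$prediction[preds$class_index == 0]
  expect_equal(lim$intervals$median[1], unname(quantile(x0, 0.5, type = 7)))
  expect_equal(lim$intervals$q25[1], unname(quantile(x0, 0.25, type = 7)))
  expect_equal(lim$intervals$lower[1], unname(quantile(x0, 0.005, type = 7)))
  expect_equal(lim$lob,
               unname(quantile(x0, c(0.005, 0.995), type = 7)))
  expect_error(determine_limits(preds[preds$class_index != 0, ], 1e-12), "Control")
  expect_error(determine_limits(preds[c(1:5, 101:200), ], 1e-12), ">= 20")
})

test_that("the learning-curve report covers every size; one repeat has zero SD", {
  fm <- blob_features(40, 3, p = 22, sep = 4, seed = 13)
  fm$class_index <- as.integer(fm$class_index)
  sp <- stratified_split(fm, 0.25, seed = 1)
  lc <- learning_curve(sp$train, sp$holdout, cnn_spec(seed = 1),
                       sizes = c(10L, 20L), n_repeats = 1L, epochs = 2L, seed = 3)
  expect_equal(lc$size, c(10, 20))
  expect_equal(lc$mse_sd, c(0, 0))
  expect_true(all(is.finite(lc$mse_mean)))
  expect_error(learning_curve(sp$train, sp$holdout, cnn_spec(),
                              sizes = 10000L, n_repeats = 1L), "ceiling")
})
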