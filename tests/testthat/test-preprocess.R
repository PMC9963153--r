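# Dense (non-sparse) re-implementation of the asymmetric-least-squares
# iteration, used as an independent oracle on short traces.
dense_asls <- function(y, lambda, p, iters) {
  n <- length(y)
  D <- diff(diag(n), differences = 2)
  P <- lambda * t(D) %*% D
  w <- rep(1, n)
  z <- y
  for (i in seq_len(iters)) {
    z <- solve(diag(w) + P, w * y)
    w <- ifelse(y > z, p, 1 - p)
  }
  z
}

test_that("AsLS equals the dense-solver oracle on short traces", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      n <- sample(5:50, 1)
      y <- cumsum(rnorm(n)) + 5 * exp(-(seq_len(n) - n / 2)^2 / 4)
      pars <- preprocess_params(asls_lambda = 10^runif(1, 0, 4),
                                asls_p = runif(1, 0.01, 0.2),
                                asls_iters = sample(1:5, 1))
      got <- baseline_asls(y, pars)$baseline
      want <- dense_asls(y, pars$asls_lambda, pars$asls_p, pars$asls_iters)
      expect_equal(got, as.numeric(want), tolerance = 1e-8)
    }
  })
})

test_that("AsLS handles degenerate and smooth inputs as expected", {
  pars <- preprocess_params()
  z <- baseline_asls(rep(0, 20), pars)
  expect_equal(z$baseline, rep(0, 20))
  expect_equal(z$corrected, rep(0, 20))
  # a pure slowly-varying curve is absorbed into the baseline
  x <- seq(0, 1, length.out = 200)
  y <- 10 + 5 * x + 2 * x^2
  out <- baseline_asls(y, preprocess_params(asls_lambda = 1e4))
  expect_lt(max(abs(out$corrected)), 0.01 * max(y))
  expect_error(baseline_asls(c(1, NA, 3)), "finite")
  expect_error(baseline_asls(c(1, 2)), "3 points")
})

test_that("Savitzky-Golay equals brute-force windowed polynomial fits", {
  withr::with_seed(4, {
    y <- rnorm(9)
    pars <- preprocess_params(savgol_window = 5, savgol_order = 2)
    fitwin <- function(w, at) {
      X <- outer(0:4, 0:2, `^`)
      beta <- solve(crossprod(X), crossprod(X, y[w]))
      sum(beta * at^(0:2))
    }
    want <- numeric(9)
    for (i in 3:7) want[i] <- fitwin((i - 2):(i + 2), 2)
    for (i in 1:2) want[i] <- fitwin(1:5, i - 1)   # edge fits, extrapolated
    for (i in 8:9) want[i] <- fitwin(5:9, i - 5)
    expect_equal(smooth_savgol(y, pars), want, tolerance = 1e-10)
  })
})

test_that("Savitzky-Golay reproduces polynomials and rejects bad windows", {
  x <- seq_len(40)
  y <- 2 + 0.5 * x - 0.03 * x^2 + 1e-3 * x^3
  expect_equal(smooth_savgol(y, preprocess_params()), y, tolerance = 1e-9)
  expect_equal(smooth_savgol(rep(7, 15), preprocess_params()), rep(7, 15))
  expect_error(smooth_savgol(rnorm(5), preprocess_params(savgol_window = 11)),
               "window")
  expect_error(preprocess_params(savgol_window = 4), "odd")
  expect_error(preprocess_params(savgol_order = 11), "order")
})

test_that("silicon normalization pins the window maximum to one and is scale-free", {
  wn <- seq(300, 1800, 5)
  y <- 0.5 + exp(-(wn - 520)^2 / 50) * 3.2
  pars <- preprocess_params()
  z <- normalize_silicon(y, wn, pars)
  expect_equal(max(z[abs(wn - 520) <= 15]), 1)
  expect_equal(normalize_silicon(2 * y, wn, pars), z)
  expect_error(normalize_silicon(-y, wn, pars), "positive")
  expect_error(normalize_silicon(y, wn + 5000, pars), "window")
})

test_that("normalization cancels multiplicative gains exactly when noise-free", {
  cfg <- generator_config(noise_sd = 0, wavenumbers = seq(300, 1800, 5))
  a <- simulate_spectrum(cfg, 1e-9, surface_gain = 0.7)
  b <- simulate_spectrum(cfg, 1e-9, surface_gain = 1.9)
  pars <- preprocess_params()
  na <- normalize_silicon(a$intensity[[1]], wavenumbers(a), pars)
  nb <- normalize_silicon(b$intensity[[1]], wavenumbers(b), pars)
  expect_equal(na, nb, tolerance = 1e-9)
})

test_that("the preprocessing chain preserves shape and flags re-application", {
  ds <- simulate_dataset(tiny_cfg(seed = 5))
  out <- preprocess_dataset(ds)
  expect_equal(nrow(out), nrow(ds))
  expect_equal(wavenumbers(out), wavenumbers(ds))
  expect_identical(out$spectrum_id, ds$spectrum_id)
  # silicon window maximum is exactly 1 for every spectrum
  m <- intensity_matrix(out)
  si <- abs(wavenumbers(out) - 520) <= 15
  expect_equal(unname(apply(m[, si], 1, max)), rep(1, nrow(m)))
  expect_warning(preprocess_dataset(out), "already")
  empty <- sers_dataset(tibble::tibble(), list(), seq(300, 1800, 5))
  expect_equal(nrow(preprocess_dataset(empty)), 0L)
})
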