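g21 <- wl_grid(1000, 10, 21)
lam21 <- wavelengths(g21)

test_that("offset baseline subtracts the per-spectrum minimum", {
  expect_equal(offset_baseline(c(0.4, 0.6, 1.4)), c(0, 0.2, 1.0))
  expect_equal(offset_baseline(rep(3.2, 7)), rep(0, 7))
  x <- c(0, 0.2, 1.0)
  expect_equal(offset_baseline(x), x)  # idempotent once min is zero
  M <- rbind(c(1, 2, 3), c(-1, 0, 1))
  expect_equal(offset_baseline(M), rbind(c(0, 1, 2), c(0, 1, 2)))
})

test_that("area normalization yields unit L1 norm and rejects zero spectra", {
  expect_equal(area_normalize(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  set.seed(3)
  x <- rnorm(50)
  expect_equal(sum(abs(area_normalize(x))), 1, tolerance = 1e-12)
  expect_error(area_normalize(c(0, 0, 0)), "degenerate")
})

test_that("SNV standardizes each spectrum and is affine-invariant", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(4)
  M <- matrix(rnorm(5 * 40), 5)
  S <- snv(M)
  expect_equal(rowMeans(S), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(S, 1, sd), rep(1, 5), tolerance = 1e-12)
  expect_equal(snv(3.7 * M[1, ] + 0.9), S[1, ], tolerance = 1e-10)
  expect_error(snv(rep(1, 10)), "degenerate")
})

test_that("detrend removes quadratic wavelength trends exactly", {
  l <- scaled_lambda(g21)
  quad <- 0.3 + 1.2 * l - 0.7 * l^2
  expect_equal(detrend(quad, g21), rep(0, 21), tolerance = 1e-9)
  set.seed(5)
  x <- rnorm(21)
  r <- detrend(x, g21)
  # least-squares residuals are orthogonal to the polynomial basis
  for (basis in list(rep(1, 21), l, l^2))
    expect_lt(abs(sum(r * basis)), 1e-8)
  # matches an independent lm() polynomial-fit oracle
  oracle <- residuals(lm(x ~ l + I(l^2)))
  expect_equal(r, unname(oracle), tolerance = 1e-10)
  expect_lte(var(r), var(x))
})

test_that("MSC inverts its affine scatter model and is idempotent", {
  set.seed(6)
  ref <- 0.4 + cumsum(abs(rnorm(30, 0.02)))
  x <- 2 * ref + 0.3
  expect_equal(msc(x, ref), ref, tolerance = 1e-10)
  expect_equal(msc(ref, ref), ref, tolerance = 1e-12)
  y <- ref + rnorm(30, 0, 0.05)
  expect_equal(msc(msc(y, ref), ref), msc(y, ref), tolerance = 1e-10)
})

test_that("EMSC inverts affine + polynomial baseline distortions", {
  set.seed(7)
  ref <- 0.4 + cumsum(abs(rnorm(21, 0.05)))
  l <- scaled_lambda(g21)
  x <- 1.5 * ref + 0.2 + 0.1 * l
  expect_equal(emsc(x, ref, g21), ref, tolerance = 1e-9)
  expect_equal(emsc(ref, ref, g21), ref, tolerance = 1e-10)
  x2 <- 0.8 * ref - 0.1 + 0.2 * l - 0.15 * l^2
  expect_equal(emsc(x2, ref, g21), ref, tolerance = 1e-9)
  # with no polynomial distortion EMSC agrees with the MSC oracle
  x3 <- 2 * ref + 0.3
  expect_equal(emsc(x3, ref, g21), msc(x3, ref), tolerance = 1e-9)
})

test_that("Savitzky-Golay derivatives are exact on design polynomials", {
  s <- 0.037  # absorbance per nm
  ramp <- s * (lam21 - 1000)
  d1 <- savgol_derivative(ramp, 1, 2, 5, g21)
  expect_equal(d1, rep(s, 21), tolerance = 1e-12)
  expect_equal(savgol_derivative(rep(0.8, 21), 1, 2, 5, g21), rep(0, 21))
  # quadratic: analytic derivative oracle, exact including edges
  quad <- 2 + 0.01 * lam21 + 3e-6 * lam21^2
  d <- savgol_derivative(quad, 1, 2, 3, g21)
  expect_equal(d, 0.01 + 6e-6 * lam21, tolerance = 1e-9)
  expect_error(savgol_derivative(ramp, 1, 2, 4, g21), "invalid")
  expect_error(savgol_derivative(ramp, 3, 2, 5, g21), "invalid")
})

test_that("Norris gap derivative matches finite differences on the interior", {
  s <- -0.012
  ramp <- s * lam21 + 4
  for (gap in c(1, 3, 7))
    expect_equal(norris_gap_derivative(ramp, 1, gap, g21), rep(s, 21),
                 tolerance = 1e-12)
  expect_equal(norris_gap_derivative(rep(1.1, 21), 1, 5, g21), rep(0, 21))
  set.seed(8)
  x <- rnorm(21)
  d <- norris_gap_derivative(x, 1, 1, g21)
  oracle <- (x[3:21] - x[1:19]) / (2 * 10)  # central finite difference
  expect_equal(d[2:20], oracle)
  expect_error(norris_gap_derivative(x, 1, 11, g21), "too large")
  expect_error(norris_gap_derivative(x, 2, 1, g21), "first order")
})

test_that("chain parser implements the published token grammar", {
  ch <- parse_chain("Offset|Area|SNV+D|SG-1-2-3")
  expect_length(ch$steps, 5)
  expect_identical(vapply(ch$steps, `[[`, "", "type"),
                   c("offset", "area", "snv", "detrend", "sg"))
  expect_equal(ch$steps[[5]][c("deriv", "poly", "window")],
               list(deriv = 1L, poly = 2L, window = 3L))
  expect_length(parse_chain("None")$steps, 0)
  ng <- parse_chain("NG-1-13")$steps[[1]]
  expect_equal(ng[c("type", "deriv", "gap")],
               list(type = "ng", deriv = 1L, gap = 13L))
  emscd <- parse_chain("EMSC+D")
  expect_identical(vapply(emscd$steps, `[[`, "", "type"),
                   c("emsc", "detrend"))
  # irregular zeroth-derivative smoothing tokens are accepted, low-confidence
  sm <- parse_chain("SG1-2-2")$steps[[1]]
  expect_equal(sm$deriv, 0L)
  expect_true(sm$low_confidence)
  expect_true(sm$window %% 2 == 1 && sm$window > sm$poly)
  expect_error(parse_chain("Offset|WAVELET"), "WAVELET")
})

test_that("every published model configuration parses and applies", {
  cfg <- model_configs()
  expect_equal(nrow(cfg), 48)
  set.seed(9)
  X <- matrix(runif(4 * 101, 0.3, 1.2), 4)
  g <- wl_grid(1000, 15, 101)
  for (i in seq_len(nrow(cfg))) {
    out <- apply_chain(cfg$chain[i], X, X[1:2, ], g)
    expect_identical(dim(out$calibration), dim(X))
  }
})

test_that("chains fit on calibration only and transform deterministically", {
  set.seed(10)
  g <- tiny_grid(31)
  Xc <- matrix(runif(8 * 31, 0.3, 1.2), 8)
  Xv <- matrix(runif(4 * 31, 0.3, 1.2), 4)
  # empty chain is the identity
  out <- apply_chain("None", Xc, Xv, g)
  expect_equal(out$calibration, Xc)
  expect_equal(out$validation, Xv)
  # MSC reference is the calibration mean: that spectrum passes unchanged
  fitted <- fit_chain(parse_chain("MSC"), Xc, g)
  expect_equal(drop(chain_transform(fitted, colMeans(Xc))), colMeans(Xc),
               tolerance = 1e-10)
  # determinism and no leakage: batch transform equals one-at-a-time
  ch <- parse_chain("Offset|SNV|MSC|SG-1-2-5")
  f1 <- fit_chain(ch, Xc, g)
  batch <- chain_transform(f1, Xv)
  expect_identical(batch, chain_transform(f1, Xv))
  onebyone <- t(sapply(seq_len(nrow(Xv)), function(i)
    drop(chain_transform(f1, Xv[i, , drop = FALSE]))))
  expect_equal(batch, onebyone, tolerance = 1e-12)
  expect_error(chain_transform(parse_chain("MSC"), Xv, g), "fitted")
})
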