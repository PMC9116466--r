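test_that("hand-placed escape records land in the worked profile bins", {
  fx <- make_fixture("toy-escapes")
  spec <- profile_spec()
  Br <- score_backward(fx$escapes, spec, fx$N, fx$launch)
  expect_length(Br, 24)
  # unit weight at r = 0.6 mm: annulus [0.5, 0.9), area pi*(0.81 - 0.25)
  expect_equal(Br[1], 1 / (pi * (0.9^2 - 0.5^2)), tolerance = 1e-9)
  expect_equal(Br[1], 0.56841, tolerance = 1e-4)
  expect_true(all(Br[-1] == 0))
  Fr <- score_forward(fx$escapes, spec, fx$N, fx$launch)
  expect_length(Fr, 25)
  expect_equal(Fr[1], 1.98944, tolerance = 1e-4)
  expect_equal(Fr[1], 1 / (2 * pi * 0.5 * 0.4^2), tolerance = 1e-9)
  Lz <- score_lateral(fx$escapes, spec, fx$N, fx$launch)
  expect_length(Lz, 200)
  expect_equal(Lz[1], 1.0)
  expect_true(all(Lz[-1] == 0))
})

test_that("profiles clip out-of-range and wide-y records", {
  spec <- profile_spec()
  esc <- data.frame(x = c(12, 3), y = c(0, 6), z = c(0, 0.05),
                    ux = 0, uy = 0, uz = c(-1, 0),
                    w = 1, face = factor(c("z_min", "x_max"),
                                         levels = levels(make_fixture("toy-escapes")$escapes$face)))
  expect_true(all(score_backward(esc, spec, 1, c(0, 0)) == 0))  # r >= 10
  expect_true(all(score_lateral(esc, spec, 1, c(0, 0)) == 0))   # |dy| > 5
})

test_that("scoring is additive in escapes and scales as 1/N", {
  set.seed(3)
  n <- 500
  esc <- data.frame(x = runif(n, -12, 12), y = runif(n, -12, 12),
                    z = runif(n, 0, 25), ux = 0, uy = 0, uz = 1,
                    w = runif(n),
                    face = factor(sample(c("z_min", "z_max", "x_max"), n, TRUE),
                                  levels = levels(make_fixture("toy-escapes")$escapes$face)))
  spec <- profile_spec()
  a <- esc[1:200, ]; b <- esc[201:n, ]
  for (f in list(score_backward, score_forward, score_lateral)) {
    full <- f(esc, spec, 1000, c(0, 0))
    expect_equal(f(a, spec, 1000, c(0, 0)) + f(b, spec, 1000, c(0, 0)),
                 full, tolerance = 1e-12)
    expect_equal(f(esc, spec, 2000, c(0, 0)), full / 2, tolerance = 1e-12)
  }
  # total-weight consistency for the backward profile
  Br <- score_backward(esc, spec, 1000, c(0, 0))
  edges <- attr(Br, "edges")
  r <- sqrt(esc$x^2 + esc$y^2)
  inb <- esc$face == "z_min" & r >= edges[1] & r < edges[length(edges)]
  expect_equal(sum(Br * pi * diff(edges^2) * 1000), sum(esc$w[inb]),
               tolerance = 1e-9)
})

test_that("feature vectors assemble the documented blocks", {
  spec <- profile_spec()
  profs <- structure(list(Br = rep(2, 24), Fr = rep(1.5, 25),
                          Lz = rep(3, 200), N = 100),
                     class = "intensity_profiles")
  fv <- build_features(profs, spec)
  expect_length(fv, 40)
  blocks <- attr(fv, "blocks")
  expect_equal(lengths(blocks), c(Bf = 26L, Ff = 2L, Lf = 12L))
  expect_equal(sort(unname(unlist(blocks))), 1:40)
  expect_length(attr(fv, "flagged"), 0)
  # constant profiles: raw bins pass through, means log-transform exactly,
  # zero variances floor at ln(eps * max)
  expect_equal(unname(fv[1:24]), rep(2, 24))
  expect_equal(unname(fv["Bf_lnm"]), log(2))
  # zero variance floors at eps times the block's largest positive value
  expect_equal(unname(fv["Bf_lnv"]), log(spec$ln_eps_rel * 2))
  expect_equal(unname(fv["Ff_lnm"]), log(1.5))
  expect_equal(unname(fv["Ff_lnv"]), log(spec$ln_eps_rel * 1.5))
  # constant lateral profile survives smoothing and downsampling unchanged
  expect_equal(unname(fv[sprintf("Lf_%02d", 0:9)]), rep(log(3), 10))
  expect_equal(unname(fv["Lf_lnm"]), log(3))
})

test_that("empty detection blocks are flagged", {
  spec <- profile_spec()
  profs <- structure(list(Br = rep(1, 24), Fr = rep(0, 25),
                          Lz = rep(1, 200), N = 10),
                     class = "intensity_profiles")
  fv <- build_features(profs, spec)
  expect_identical(attr(fv, "flagged"), "Ff")
  expect_true(all(is.na(fv[c("Ff_lnm", "Ff_lnv")])))
  expect_true(all(is.finite(fv[attr(fv, "blocks")$Bf])))
})

test_that("standardization gives exact population moments and round-trips", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 8))
  s <- fit_standardizer(X)
  Z <- apply_standardizer(s, X)
  expect_equal(Z[, "a"], c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_lt(max(abs(colMeans(Z))), 1e-12)
  expect_lt(max(abs(sqrt(colMeans(Z^2)) - 1)), 1e-12)
  # single vectors transform with the stored moments
  z1 <- apply_standardizer(s, X[2, ])
  expect_equal(as.numeric(z1), as.numeric(Z[2, ]))
})

test_that("constant features are dropped with a record", {
  X <- cbind(a = c(1, 2, 3), const = c(4, 4, 4))
  expect_warning(s <- fit_standardizer(X), "constant")
  expect_identical(s$dropped, "const")
  expect_equal(ncol(apply_standardizer(s, X)), 1L)
})

test_that("train-fitted scalers leave held-out folds off-center", {
  set.seed(2)
  X <- matrix(rnorm(200), 50, 4)
  s <- fit_standardizer(X[1:30, , drop = FALSE], "train-folds")
  Zte <- apply_standardizer(s, X[31:50, , drop = FALSE])
  expect_gt(max(abs(colMeans(Zte))), 1e-6)
  expect_identical(s$fitted_on, "train-folds")
})
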