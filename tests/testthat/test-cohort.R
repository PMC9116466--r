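test_that("structural sampling reproduces the population model", {
  set.seed(101)
  n <- 1e4
  draws <- replicate(n, {
    p <- sample_structure("normal")
    c(p$t_dermis, p$t_subcut, p$c_th, p$bvtv)
  })
  expect_true(all(draws[1, ] >= 1 & draws[1, ] <= 2))
  expect_true(all(draws[2, ] >= 1 & draws[2, ] <= 6))
  # stage marginals (normal): C.Th 0.804 +/- 0.149 mm, BV/TV 13.4 +/- 2.8 %
  expect_lt(abs(mean(draws[3, ]) - 0.804), 0.01)
  expect_lt(abs(sd(draws[3, ]) - 0.149), 0.005)
  expect_lt(abs(mean(100 * draws[4, ]) - 13.4), 0.15)
  expect_lt(abs(cor(draws[3, ], draws[4, ]) - 0.54), 0.03)
})

test_that("the cortical-trabecular correlation can be switched off", {
  set.seed(77)
  draws <- replicate(5e3, {
    p <- sample_structure("osteopenia", correlation = 0)
    c(p$c_th, p$bvtv)
  })
  expect_lt(abs(cor(draws[1, ], draws[2, ])), 0.04)
})

test_that("bone scattering follows the mineral-density relation", {
  expect_equal(mu_s_from_mbmd(1.2), 20.584)
  expect_equal(round(mu_s_from_mbmd(1.2), 2), 20.58)
  expect_equal(mu_s_from_mbmd(0.74 / 17.77), 0)
  expect_error(mu_s_from_mbmd(0), "negative scattering")
})

test_that("optical draws respect the literature ranges and tissue identities", {
  set.seed(5)
  for (i in 1:200) {
    op <- sample_optics()
    expect_identical(unclass(op$marrow), unclass(op$subcutaneous))
    expect_identical(unclass(op$cortical), unclass(op$trabecular))
    expect_equal(op$cortical$n, 1.55)
    expect_equal(op$dermis$n, 1.4)
    expect_true(op$dermis$mu_a >= 0.0063 && op$dermis$mu_a <= 0.0856)
    expect_true(op$dermis$mu_s >= 14.20 && op$dermis$mu_s <= 25.06)
    expect_true(op$subcutaneous$mu_a >= 0.0049 && op$subcutaneous$mu_a <= 0.0124)
    expect_true(op$subcutaneous$mu_s >= 8.30 && op$subcutaneous$mu_s <= 13.96)
    expect_equal(op$cortical$mu_a, 0.0237)
    expect_equal(op$cortical$mu_s, 20.584)
  }
})

test_that("areal BMD reduces correctly in the limiting geometries", {
  base <- list(bvtv = 0.134, c_th = 0.804, l_obs = 17.15, mbmd = 1.2)
  expect_equal(compute_abmd(modifyList(base, list(bvtv = 1))), 1.2)
  expect_equal(compute_abmd(modifyList(base, list(c_th = 0))), 1.2 * 0.134)
  expect_equal(compute_abmd(base), 0.34653, tolerance = 1e-4)
  expect_error(compute_abmd(modifyList(base, list(c_th = 9))), "overlap")
})

test_that("areal BMD is monotone in volume fraction and cortical thickness", {
  bv <- seq(0.02, 0.3, length.out = 12)
  ct <- seq(0.1, 1.5, length.out = 12)
  for (c0 in c(0.3, 0.8)) {
    a <- vapply(bv, function(b) compute_abmd(list(bvtv = b, c_th = c0,
                                                  l_obs = 17.15, mbmd = 1.2)),
                numeric(1))
    expect_true(all(diff(a) > 0))
  }
  for (b0 in c(0.08, 0.2)) {
    a <- vapply(ct, function(cc) compute_abmd(list(bvtv = b0, c_th = cc,
                                                   l_obs = 17.15, mbmd = 1.2)),
                numeric(1))
    expect_true(all(diff(a) > 0))
  }
})

test_that("sampled aBMD labels stay inside the physical range", {
  set.seed(9)
  ab <- replicate(300, {
    st <- sample(c("normal", "osteopenia", "osteoporosis"), 1)
    compute_abmd(sample_structure(st))
  })
  expect_true(all(ab > 0 & ab < 1.2))
})

test_that("assembly nests the tissue shells without gaps", {
  set.seed(3)
  p <- sample_structure("normal")
  op <- sample_optics()
  vol <- make_fixture("tiny-trabecular")
  attr(vol, "voxel_size") <- 0.098
  m <- assemble(p, op, vol)
  # total extent: bone cross-section plus both soft-tissue layers each side
  expect_equal(m$extent[1], p$l_obs + 2 * (p$t_dermis + p$t_subcut),
               tolerance = 2 * m$lv)
  expect_equal(m$extent[1], m$extent[3])
  expect_equal(m$extent[2], p$y_extent, tolerance = m$lv)
  expect_identical(model_label_at(m, c(m$extent[1] / 2, m$extent[2] / 2, m$lv / 2)),
                   "dermis")
  expect_true(model_label_at(m, m$extent / 2) %in% c("trabecular", "marrow"))
  # every interior point maps to exactly one of the five labels
  set.seed(12)
  pts <- cbind(runif(2000, 0, m$extent[1]), runif(2000, 0, m$extent[2]),
               runif(2000, 0, m$extent[3]))
  labs <- apply(pts, 1, function(x) model_label_at(m, x))
  expect_true(all(labs %in% c("dermis", "subcutaneous", "cortical",
                              "trabecular", "marrow")))
  expect_setequal(unique(labs), c("dermis", "subcutaneous", "cortical",
                                  "trabecular", "marrow"))
})

test_that("assembly enforces the tissue-optics identities", {
  set.seed(4)
  p <- sample_structure("normal")
  op <- sample_optics()
  op$marrow <- optical_props(0.5, 5, 0.9, 1.4)   # break marrow = subcutaneous
  vol <- make_fixture("tiny-trabecular")
  expect_error(assemble(p, op, vol), "marrow optics")
})
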