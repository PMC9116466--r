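test_that("child seeds are deterministic, in range, and well separated", {
  s1 <- child_seed(1, 2, 3)
  expect_identical(s1, child_seed(1, 2, 3))
  seeds <- c(outer(1:20, 1:5, function(i, s) mapply(child_seed, 1, s, i)))
  expect_true(all(seeds >= 1 & seeds < 2^31))
  expect_equal(anyDuplicated(seeds), 0L)
  expect_false(child_seed(1, 1, 1) == child_seed(2, 1, 1))
})

test_that("configurations round-trip through YAML unchanged", {
  cfg <- pipeline_config("desk", master_seed = 7,
                         cohort = list(n_models = 12),
                         sim = list(n_photons = 1000))
  path <- tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(unclass(cfg2), unclass(cfg))
})

test_that("profiles encode the printed study constants", {
  ref <- pipeline_config("reference")
  expect_equal(ref$cohort$n_models, 1211)
  expect_equal(ref$cohort$l_obs, 17.15)
  expect_equal(ref$cohort$y_extent, 35.28)
  expect_equal(ref$cohort$mbmd, 1.2)
  expect_equal(ref$rd$voxel_size, 0.0245)
  expect_equal(ref$rd$shape, 720)
  expect_equal(ref$sim$n_photons, 1e7)
  desk <- pipeline_config("desk")
  # the desk profile only reduces problem sizes, never the physics
  expect_equal(desk$cohort$l_obs, ref$cohort$l_obs)
  expect_equal(desk$cohort$mbmd, ref$cohort$mbmd)
  expect_lt(desk$sim$n_photons, ref$sim$n_photons)
  expect_lt(desk$rd$shape, ref$rd$shape)
})

test_that("fixtures are deterministic and match their contracts", {
  sm <- make_fixture("slab-model")
  expect_s3_class(sm, "tissue_model")
  expect_equal(unname(sm$optics[1, "mu_s"]), 0)
  tv <- make_fixture("tiny-trabecular")
  expect_equal(measure_bvtv(tv), 0.5)
  expect_equal(dim(tv), c(32L, 32L, 32L))
  te <- make_fixture("toy-escapes")
  expect_equal(nrow(te$escapes), 3)
  tf1 <- make_fixture("toy-features", seed = 3)
  tf2 <- make_fixture("toy-features", seed = 3)
  expect_identical(tf1$X, tf2$X)
  expect_error(make_fixture("nope"), "arg")
})

test_that("the cohort manifest is reproducible and complete", {
  cfg <- pipeline_config("desk", master_seed = 11,
                         cohort = list(n_models = 25))
  m1 <- sample_cohort(cfg)
  m2 <- sample_cohort(cfg)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 25)
  expect_true(all(m1$abmd > 0 & m1$abmd < 1.2))
  expect_true(all(m1$stage %in% c("normal", "osteopenia", "osteoporosis")))
  expect_true(all(m1$t_dermis >= 1 & m1$t_dermis <= 2))
  # a different master seed gives a different cohort
  m3 <- sample_cohort(pipeline_config("desk", master_seed = 12,
                                      cohort = list(n_models = 25)))
  expect_false(identical(m1$c_th, m3$c_th))
})

test_that("the pipeline completes end-to-end on a miniature run", {
  cfg <- pipeline_config("desk", master_seed = 3,
                         cohort = list(n_models = 14),
                         rd = list(shape = 32, n_pool = 3, recalibrate = FALSE),
                         sim = list(n_photons = 1500),
                         ml = list(grids = list(
                           RR = data.frame(alpha = 1e-3),
                           SVM = expand.grid(gamma = c(0.01, 0.1), cost = 100,
                                             epsilon = 0.01),
                           RF = data.frame(num_trees = 50, min_node = 5,
                                           mtry_frac = NA),
                           GTB = data.frame(nrounds = 30, eta = 0.3,
                                            max_depth = 3, min_child_weight = 1,
                                            subsample = 1, colsample_bytree = 1)),
                           k = 5, run_ablation = FALSE))
  out <- file.path(tempdir(), "osteosim-mini")
  s1 <- run_pipeline(cfg, out_dir = out)
  expect_true(all(c("algo_r2", "best_algorithm", "final", "n_models",
                    "n_flagged", "uth_coeffs") %in% names(s1)))
  expect_equal(s1$n_models, 14)
  expect_true(is.finite(s1$final$regression_r2))
  expect_true(file.exists(file.path(out, "summary.json")))
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_true(file.exists(file.path(out, "features.csv")))
  # determinism of the whole pipeline under the master seed
  s2 <- run_pipeline(cfg)
  s1$elapsed_s <- s2$elapsed_s <- NULL
  expect_equal(s1, s2, tolerance = 1e-12)
})
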