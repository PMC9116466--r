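test_that("specular reflectance and launch weight follow normal-incidence Fresnel", {
  expect_equal(specular_reflectance(1, 1.4), (0.4 / 2.4)^2)
  expect_equal(specular_reflectance(1, 1.4), 0.027778, tolerance = 1e-5)
  expect_equal(specular_reflectance(1.4, 1.4), 0)
})

test_that("Fresnel reflectance handles matched media and total internal reflection", {
  f <- fresnel_unpolarized(1, 1.4, 1)
  expect_equal(f$R, 0.027778, tolerance = 1e-5)
  expect_equal(fresnel_unpolarized(1.4, 1.4, 0.3)$R, 0)
  # critical angle for 1.55 -> 1.4: sin = 1.4/1.55
  cos_crit <- sqrt(1 - (1.4 / 1.55)^2)
  expect_equal(fresnel_unpolarized(1.55, 1.4, cos_crit * 0.9)$R, 1)
  expect_lt(fresnel_unpolarized(1.55, 1.4, cos_crit * 1.1)$R, 1)
})

test_that("step lengths are exponential with the transport mean free path", {
  expect_equal(step_size(4, 6, xi = exp(-1)), 0.1)
  expect_equal(step_size(1, 9, xi = 1), 0)
  expect_error(step_size(0, 0), "vacuum")
  set.seed(8)
  s <- step_size(0.5, 9.5, xi = runif(1e6))
  se <- 0.1 / sqrt(1e6)
  expect_lt(abs(mean(s) - 0.1), 3 * se)
})

test_that("voxel boundary distances match the closed-form geometry", {
  lv <- 0.0245
  d1 <- distance_to_boundary(c(0, 0, 0), c(0, 0, 1), lv)
  expect_equal(d1$db, lv / 2)
  expect_equal(d1$axis, 3)
  expect_equal(d1$dir, 1)
  d2 <- distance_to_boundary(c(0, 0, 0.006125), c(0, 0, -1), lv)
  expect_equal(d2$db, 0.018375)
  expect_equal(d2$dir, -1)
  d3 <- distance_to_boundary(c(0, 0, 0), c(1, 0, 1) / sqrt(2), lv)
  expect_equal(d3$db, (lv / 2) / (1 / sqrt(2)), tolerance = 1e-12)
  expect_equal(d3$axis, 1)   # exact tie broken toward the lower axis index
  expect_error(distance_to_boundary(c(0, 0, 0), c(0, 0, 0), lv), "zero")
})

test_that("Henyey-Greenstein inversion and sampling match theory", {
  expect_equal(hg_cosine(0.9, 0.5), 0.98550, tolerance = 1e-5)
  expect_equal(hg_cosine(0, c(0, 0.5, 1)), c(-1, 0, 1))
  for (g in c(0, 0.5, 0.9)) {
    x <- sample_hg(1e6, g, seed = 17)
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - g), 3 * se)
    expect_true(all(x >= -1 & x <= 1))
  }
})

test_that("unscattered transmission through an absorbing slab is Beer-Lambert", {
  m <- make_fixture("slab-model")      # mu_a = 0.5/mm, 2 mm, mu_s = 0, n = 1
  N <- 1e5
  r <- run_transport(m, sim_config(n_photons = N, seed = 7, mode = "voxel"))
  Tr <- sum(r$escapes$w[r$escapes$face == "z_max"]) / N
  p <- exp(-0.5 * 2)
  expect_lt(abs(Tr - p), 3 * sqrt(p * (1 - p) / N))
  # no scattering: the beam stays collimated
  expect_true(all(abs(r$escapes$uz[r$escapes$face == "z_max"] - 1) < 1e-9))
})

test_that("energy is conserved to float precision in every regime", {
  for (spec in list(
    list(ly = data.frame(thickness = 1, mu_a = 0.1, mu_s = 10, g = 0.9, n = 1.4), N = 2e4),
    list(ly = data.frame(thickness = c(0.5, 1), mu_a = c(0.2, 0.05),
                         mu_s = c(15, 8), g = c(0.8, 0.9), n = c(1.4, 1.55)), N = 2e4))) {
    r <- run_transport(slab_model(spec$ly, lv = 0.05, lateral = 30),
                       sim_config(n_photons = spec$N, seed = 3, mode = "voxel"))
    expect_lt(abs(r$specular + r$absorbed + r$escaped_weight - r$n_launched),
              1e-6 * r$n_launched)
  }
})

test_that("a non-absorbing index-matched slab absorbs nothing", {
  ly <- data.frame(thickness = 0.5, mu_a = 0, mu_s = 10, g = 0.5, n = 1)
  N <- 1e4
  r <- run_transport(slab_model(ly, lv = 0.05, lateral = 30),
                     sim_config(n_photons = N, seed = 5, mode = "voxel"))
  expect_equal(r$absorbed, 0)
  expect_equal(r$specular, 0)
  expect_equal(r$escaped_weight, N, tolerance = 1e-9)
})

test_that("runs are reproducible under a fixed seed", {
  ly <- data.frame(thickness = 1, mu_a = 0.1, mu_s = 10, g = 0.9, n = 1.4)
  m <- slab_model(ly, lv = 0.05, lateral = 30)
  r1 <- run_transport(m, sim_config(n_photons = 5e3, seed = 99))
  r2 <- run_transport(m, sim_config(n_photons = 5e3, seed = 99))
  expect_identical(r1$escapes, r2$escapes)
  expect_identical(r1$absorbed, r2$absorbed)
})

test_that("results do not depend on the voxel size in a homogeneous medium", {
  ly <- data.frame(thickness = 1, mu_a = 0.1, mu_s = 10, g = 0.9, n = 1.4)
  N <- 2e4
  s1 <- slab_summary(run_transport(slab_model(ly, lv = 0.1, lateral = 40),
                                   sim_config(n_photons = N, seed = 1, mode = "voxel")))
  s2 <- slab_summary(run_transport(slab_model(ly, lv = 0.05, lateral = 40),
                                   sim_config(n_photons = N, seed = 2, mode = "voxel")))
  tol <- 3 * sqrt(frac_se(s1$Rd, N)^2 + frac_se(s2$Rd, N)^2)
  expect_lt(abs(s1$Rd - s2$Rd), tol)
  expect_lt(abs(s1$Td - s2$Td), tol)
})

test_that("the voxel engine agrees with an independent layered Monte Carlo", {
  cases <- list(
    data.frame(thickness = 1, mu_a = 0.1, mu_s = 10, g = 0.9, n = 1.4),
    data.frame(thickness = c(0.5, 1), mu_a = c(0.2, 0.05), mu_s = c(15, 8),
               g = c(0.8, 0.9), n = c(1.4, 1.55)),
    data.frame(thickness = c(0.4, 0.8, 0.6), mu_a = c(0.1, 0.3, 0.05),
               mu_s = c(12, 6, 15), g = c(0.7, 0.9, 0.85),
               n = c(1.37, 1.5, 1.4)))
  N <- 3e4
  for (k in seq_along(cases)) {
    ly <- cases[[k]]
    o <- mcml_layered(ly, N, seed = 10 + k)
    s <- slab_summary(run_transport(slab_model(ly, lv = 0.05, lateral = 40),
                                    sim_config(n_photons = N, seed = 20 + k,
                                               mode = "voxel")))
    expect_lt(s$lateral, 1e-3)   # lateral truncation negligible
    tol <- 3 * sqrt(2) * frac_se(max(o$Rd, o$Td), N)
    expect_lt(abs(s$Rd - o$Rd), tol)
    expect_lt(abs(s$Td - o$Td), tol)
  }
})

test_that("region acceleration matches naive voxel traversal", {
  set.seed(6)
  p <- sample_structure("normal")
  op <- sample_optics()
  u <- solve_rd(rd_params(shape = c(64, 64, 64), seed = 13))
  vol <- binarize(u, uth_from_bvtv(p$bvtv), voxel_size = 0.098)
  m <- assemble(p, op, vol)
  N <- 8e3
  sv <- run_transport(m, sim_config(n_photons = N, seed = 41, mode = "voxel"))
  sr <- run_transport(m, sim_config(n_photons = N, seed = 42, mode = "region"))
  for (r in list(sv, sr))
    expect_lt(abs(r$specular + r$absorbed + r$escaped_weight - r$n_launched),
              1e-6 * N)
  rd_v <- sum(sv$escapes$w[sv$escapes$face == "z_min"]) / N
  rd_r <- sum(sr$escapes$w[sr$escapes$face == "z_min"]) / N
  tol <- 4 * sqrt(2) * frac_se(rd_v, N)
  expect_lt(abs(rd_v - rd_r), tol)
  expect_lt(abs(sv$absorbed - sr$absorbed) / N, tol)
})
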