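#' Counter-based child seed derivation
#'
#' Fans a master seed out into independent per-stage, per-model seeds so
#' that cohorts are reproducible under partial re-runs and arbitrary
#' execution order. Pure modular arithmetic below 2^31.
#'
#' @param master master seed (integer).
#' @param stream stage index (integer, e.g. 1 = patterns, 2 = structure,
#'   3 = optics, 4 = transport, 5 = ml).
#' @param index item index within the stage.
#' @return An integer seed in \[1, 2^31 - 2\].
#' @export
child_seed <- function(master, stream, index = 0) {
  m <- 2147483563
  x <- (abs(master) %% m)
  x <- (x * 32717 + stream * 20011 + index * 9613 + 17) %% m
  x <- (x * 30103 + 7) %% m
  as.integer(x + 1)
}

#' Pipeline run configuration
#'
#' Bundles every stage's parameters. Two profiles are provided:
#' \describe{
#'   \item{reference}{the full-scale study conditions: 720^3
#'     reaction-diffusion grid at 24.5 um voxels, 1e7 photons per model,
#'     1211 models, full hyperparameter grids. Cluster-scale.}
#'   \item{desk}{a reduced configuration that preserves the pipeline
#'     end-to-end on one workstation: 64^3 pattern grid at 98 um voxels
#'     (with a re-calibrated threshold polynomial), fewer photons and
#'     models, thinned grids.}
#' }
#' Any element can be overridden via \code{...} (named nested lists are
#' merged).
#'
#' @param profile \code{"desk"} or \code{"reference"}.
#' @param master_seed master seed.
#' @param ... overrides merged into the profile defaults, e.g.
#'   \code{cohort = list(n_models = 50)}.
#' @return Nested list of class \code{run_config}.
#' @export
pipeline_config <- function(profile = c("desk", "reference"),
                            master_seed = 1, ...) {
  profile <- match.arg(profile)
  base <- list(
    profile = profile,
    master_seed = as.numeric(master_seed),
    cohort = list(n_models = if (profile == "reference") 1211 else 60,
                  stage_weights = list(normal = 1 / 3, osteopenia = 1 / 3,
                                       osteoporosis = 1 / 3),
                  l_obs = 17.15, y_extent = 35.28, mbmd = 1.2),
    rd = list(shape = if (profile == "reference") 720 else 64,
              voxel_size = if (profile == "reference") 0.0245 else 0.098,
              n_pool = 10,
              recalibrate = profile != "reference"),
    sim = list(n_photons = if (profile == "reference") 1e7 else 2e4,
               mode = "region", ambient_n = 1.0,
               roulette_threshold = 1e-4, roulette_chance = 0.1),
    features = list(),     # profile_spec() overrides
    ml = list(grids = if (profile == "reference") "default" else "quick",
              k = 10, train_fraction = 0.8,
              algorithms = c("SVM", "RR", "RF", "GTB"),
              standardize = "train-folds",
              run_ablation = TRUE)
  )
  ov <- list(...)
  for (nm in names(ov)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(ov[[nm]]))
      modifyList(base[[nm]], ov[[nm]]) else ov[[nm]]
  }
  structure(base, class = "run_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()] result.
#' @param path file path.
#' @return \code{read_config} returns the parsed \code{run_config};
#'   \code{write_config} returns \code{path} invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

#' Generate a cohort manifest of structural and optical draws
#'
#' Samples \code{n_models} tissue-model parameter sets: stage (by the
#' configured weights), structural parameters and soft-tissue optical
#' properties, with the aBMD label. One row per model; per-model seeds are
#' derived from the master seed so any subset can be regenerated.
#'
#' @param config a [pipeline_config()].
#' @return data.frame manifest.
#' @export
sample_cohort <- function(config) {
  cc <- config$cohort
  n <- cc$n_models
  stages <- names(cc$stage_weights)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(child_seed(config$master_seed, 2, i))
    stage <- sample(stages, 1, prob = unlist(cc$stage_weights))
    p <- sample_structure(stage, l_obs = cc$l_obs, y_extent = cc$y_extent,
                          mbmd = cc$mbmd)
    set.seed(child_seed(config$master_seed, 3, i))
    op <- sample_optics(cc$mbmd)
    rows[[i]] <- data.frame(
      model = i, stage = stage,
      t_dermis = p$t_dermis, t_subcut = p$t_subcut,
      c_th = p$c_th, bvtv = p$bvtv, abmd = compute_abmd(p),
      dermis_mu_a = op$dermis$mu_a, dermis_mu_s = op$dermis$mu_s,
      subcut_mu_a = op$subcutaneous$mu_a, subcut_mu_s = op$subcutaneous$mu_s,
      bone_mu_a = op$cortical$mu_a, bone_mu_s = op$cortical$mu_s,
      pattern_seed = child_seed(config$master_seed, 1,
                                (i - 1) %% config$rd$n_pool + 1),
      transport_seed = child_seed(config$master_seed, 4, i))
  }
  do.call(rbind, rows)
}

manifest_structure <- function(row, cc) {
  structure(list(t_dermis = row$t_dermis, t_subcut = row$t_subcut,
                 c_th = row$c_th, bvtv = row$bvtv, stage = row$stage,
                 l_obs = cc$l_obs, y_extent = cc$y_extent, mbmd = cc$mbmd),
            class = "structural_params")
}

manifest_optics <- function(row) {
  dermis <- optical_props(row$dermis_mu_a, row$dermis_mu_s, 0.9, 1.4)
  subcut <- optical_props(row$subcut_mu_a, row$subcut_mu_s, 0.9, 1.4)
  bone <- optical_props(row$bone_mu_a, row$bone_mu_s, 0.9, 1.55)
  list(dermis = dermis, subcutaneous = subcut, cortical = bone,
       trabecular = bone, marrow = subcut)
}

#' Run the full simulation-to-prediction pipeline
#'
#' Executes cohort sampling, trabecular pattern generation (a pool of
#' reaction-diffusion patterns shared across models, each thresholded at
#' the model's own BV/TV), tissue assembly, Monte Carlo transport, feature
#' extraction, and the machine-learning stage (train/test split, per-
#' algorithm grid search, feature-block ablation, final cross-validation
#' with agreement statistics).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, writes
#'   \code{manifest.csv}, \code{features.csv} and \code{summary.json}.
#' @param verbose print per-stage progress.
#' @return A summary list: per-algorithm test r^2 (\code{algo_r2}),
#'   selected algorithm, its CV mean/sd, \code{ablation} map,
#'   \code{final} agreement report (r^2, mean difference, limits of
#'   agreement), \code{n_models}, \code{n_flagged}, \code{uth_coeffs}.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t_start <- Sys.time()

  rd_cfg <- config$rd
  n_pool <- rd_cfg$n_pool
  shape <- rep(round(rd_cfg$shape), 3)
  say("patterns: solving %d reaction-diffusion fields at %d^3", n_pool, shape[1])
  pool <- vector("list", n_pool)
  for (k in seq_len(n_pool)) {
    pk <- rd_params(shape = shape,
                    seed = child_seed(config$master_seed, 1, k))
    pool[[k]] <- solve_rd(pk)
  }
  uth_coeffs <- c(-7.662, 1.645, -0.452, 0.604)
  if (isTRUE(rd_cfg$recalibrate)) {
    say("patterns: re-calibrating threshold polynomial on the pool")
    thr <- default_calibration_thresholds()
    bv <- sapply(thr, function(t) mean(vapply(pool, function(u) mean(u >= t),
                                              numeric(1))))
    fit <- lm(thr ~ poly(bv, 3, raw = TRUE))
    uth_coeffs <- rev(unname(coef(fit)))
  }

  manifest <- sample_cohort(config)
  n <- nrow(manifest)
  say("cohort: %d models", n)

  spec <- do.call(profile_spec, config$features)
  sim_cfg <- config$sim
  feats <- vector("list", n)
  flagged <- logical(n)
  blocks <- NULL
  for (i in seq_len(n)) {
    row <- manifest[i, ]
    p <- manifest_structure(row, config$cohort)
    u <- pool[[(i - 1) %% n_pool + 1]]
    vol <- binarize(u, uth_from_bvtv(row$bvtv, uth_coeffs),
                    voxel_size = rd_cfg$voxel_size)
    model <- assemble(p, manifest_optics(row), vol, seed = row$transport_seed)
    cfg <- sim_config(n_photons = sim_cfg$n_photons,
                      seed = row$transport_seed,
                      ambient_n = sim_cfg$ambient_n,
                      roulette_threshold = sim_cfg$roulette_threshold,
                      roulette_chance = sim_cfg$roulette_chance,
                      mode = sim_cfg$mode)
    run <- run_transport(model, cfg)
    fv <- build_features(score_profiles(run, spec), spec)
    flagged[i] <- length(attr(fv, "flagged")) > 0
    if (is.null(blocks)) {
      blocks <- attr(fv, "blocks")
      fnames <- names(fv)
    }
    feats[[i]] <- as.numeric(fv)
    if (verbose && i %% 10 == 0) say("  simulated %d / %d models", i, n)
  }
  X <- do.call(rbind, feats)
  colnames(X) <- fnames
  keep <- !flagged
  say("features: %d models kept, %d flagged (empty detection block)",
      sum(keep), sum(!keep))
  ds <- cohort_dataset(X[keep, , drop = FALSE], manifest$abmd[keep],
                       blocks = blocks,
                       provenance = list(master_seed = config$master_seed,
                                         profile = config$profile))

  ml <- config$ml
  grids <- if (identical(ml$grids, "quick")) quick_grids()
           else if (identical(ml$grids, "default")) default_grids()
           else ml$grids
  sp <- split_dataset(ds, ml$train_fraction,
                      seed = child_seed(config$master_seed, 5, 1))
  algo_r2 <- algo_cv_r2 <- numeric(0)
  cv_results <- list()
  for (alg in ml$algorithms) {
    say("ml: tuning %s", alg)
    cv <- tune_and_fit(sp$train, alg, grids, k = ml$k,
                       seed = child_seed(config$master_seed, 5, 2),
                       standardize = ml$standardize)
    cv_results[[alg]] <- cv
    algo_r2[alg] <- evaluate_r2(sp$test$y, predict(cv, sp$test))
    # out-of-fold score over the whole cohort with the tuned parameters:
    # a lower-variance basis for comparing algorithms at reduced scale
    algo_cv_r2[alg] <- final_cv(ds, alg, cv$best_params, k = ml$k,
                                seed = child_seed(config$master_seed, 5, 4),
                                standardize = ml$standardize)$regression_r2
  }
  best_alg <- names(algo_r2)[which.max(algo_r2)]

  abl <- NULL
  if (isTRUE(ml$run_ablation)) {
    say("ml: feature-block ablation (%s)", "SVM")
    abl <- ablation(sp$train, sp$test, "SVM", grids, k = ml$k,
                    seed = child_seed(config$master_seed, 5, 3))
  }

  say("ml: final %d-fold cross-validation (SVM)", ml$k)
  svm_cv <- cv_results[["SVM"]]
  final <- final_cv(ds, "SVM", svm_cv$best_params, k = ml$k,
                    seed = child_seed(config$master_seed, 5, 4),
                    standardize = ml$standardize)

  summary <- list(
    profile = config$profile, master_seed = config$master_seed,
    n_models = n, n_kept = sum(keep), n_flagged = sum(!keep),
    uth_coeffs = uth_coeffs,
    algo_r2 = as.list(algo_r2), algo_cv_r2 = as.list(algo_cv_r2),
    best_algorithm = names(algo_cv_r2)[which.max(algo_cv_r2)],
    best_algorithm_test = best_alg,
    algo_best_params = lapply(cv_results, function(cv) cv$best_params),
    svm_cv_mean_r2 = svm_cv$mean_r2, svm_cv_sd_r2 = svm_cv$sd_r2,
    svm_best_params = svm_cv$best_params,
    ablation = as.list(abl),
    final = list(regression_r2 = final$regression_r2,
                 mean_diff = final$mean_diff, loa = final$loa,
                 prop_bias_r = final$prop_bias_r),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    fx <- as.data.frame(X[keep, , drop = FALSE])
    fx$aBMD <- manifest$abmd[keep]
    write.csv(fx, file.path(out_dir, "features.csv"), row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  summary
}

#' Deterministic small test fixtures
#'
#' @param kind one of \code{"slab-model"} (an absorbing, non-scattering,
#'   index-matched slab for attenuation checks), \code{"tiny-trabecular"}
#'   (32^3 checkerboard mask, BV/TV exactly 0.5), \code{"toy-escapes"}
#'   (three hand-placed escape records that land in known profile bins),
#'   \code{"toy-features"} (a feature table whose labels are an exact
#'   linear function of the features).
#' @param seed seed for the random parts (toy-features).
#' @return Fixture object; type depends on \code{kind}.
#' @export
make_fixture <- function(kind = c("slab-model", "tiny-trabecular",
                                  "toy-escapes", "toy-features"),
                         seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    "slab-model" = slab_model(
      data.frame(thickness = 2, mu_a = 0.5, mu_s = 0, g = 0, n = 1.0),
      lv = 0.1, lateral = 20),
    "tiny-trabecular" = {
      idx <- as.matrix(expand.grid(x = 0:31, y = 0:31, z = 0:31))
      mask <- array((idx[, 1] + idx[, 2] + idx[, 3]) %% 2 == 0,
                    dim = c(32, 32, 32))
      trabecular_volume(mask, 0.0245)
    },
    "toy-escapes" = {
      esc <- data.frame(
        x = c(0.6, 0.1, 10.0), y = c(0, 0, 1.0), z = c(0, 30.0, 0.05),
        ux = c(0, 0, 1), uy = c(0, 0, 0), uz = c(-1, 1, 0),
        w = c(1, 1, 1),
        face = factor(c("z_min", "z_max", "x_max"),
                      levels = c("z_min", "z_max", "x_max", "x_min",
                                 "y_min", "y_max")))
      list(escapes = esc, N = 1, launch = c(x = 0, y = 0))
    },
    "toy-features" = {
      set.seed(seed)
      n <- 200; p <- 12
      X <- matrix(rnorm(n * p), n, p,
                  dimnames = list(NULL, sprintf("f%02d", 1:p)))
      beta <- seq(-1, 1, length.out = p)
      y <- drop(X %*% beta) * 0.05 + 0.5
      cohort_dataset(X, y, blocks = list(Bf = 1:6, Ff = 7:8, Lf = 9:12))
    })
}
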