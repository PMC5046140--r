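#' Pipeline configuration
#'
#' The pipeline stages communicate only through files in one output
#' directory, so each stage is independently runnable and testable. The
#' configuration is a flat key-value (YAML) file; every key has a default
#' (see [default_config()]). Keys:
#'
#' * `seed` — master integer seed for all randomness.
#' * `n_rows`, `n_cols`, `cellsize` — synthetic grid (simulate stage).
#' * `n_points` — number of sample sites; `n_background` — background
#'   cells for the distribution model.
#' * `noise_sd` — content noise on the suitability scale.
#' * `features` — maxent feature classes; `beta` — L1 regularization.
#' * `train_frac` — presence train/test split for AUC.
#' * `family` — membership family for the fuzzy stage.
#' * `t_high`, `t_low` — classification cutoffs; `fraction` —
#'   optimal-range response fraction.
#' * `combine` — rule joining growth and quality maps (min/product/mean).
#' * `allowed_classes` — land-cover class ids kept by the mask.
#' * `factors` — optional named map of factor name to raster path (when
#'   not using the simulate stage); `landcover`, `points` — optional
#'   paths likewise.
#'
#' @param path YAML file path.
#' @return A named list merging the file over the defaults.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), as.list(user))
  validate_config(cfg)
  cfg
}

#' @rdname read_pipeline_config
#' @export
default_config <- function() {
  list(
    seed = 1L,
    n_rows = 100L, n_cols = 100L, cellsize = 1,
    n_points = 200L, n_background = 2000L,
    noise_sd = 0.05,
    features = c("linear", "quadratic"),
    beta = 0.1,
    train_frac = 0.75,
    family = "kt",
    t_high = 0.7, t_low = 0.4,
    fraction = 0.8,
    combine = "min",
    allowed_classes = 1L,
    factors = NULL, landcover = NULL, points = NULL
  )
}

validate_config <- function(cfg) {
  if (!(cfg$t_low >= 0 && cfg$t_high <= 1 && cfg$t_low < cfg$t_high))
    stop("config error: need 0 <= t_low < t_high <= 1", call. = FALSE)
  if (cfg$fraction <= 0 || cfg$fraction >= 1)
    stop("config error: fraction must be in (0, 1)", call. = FALSE)
  if (cfg$seed < 0) stop("config error: seed must be a non-negative integer", call. = FALSE)
  invisible(cfg)
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yml")
  on.exit(unlink(f))
  yaml::write_yaml(cfg[order(names(cfg))], f)
  unname(tools::md5sum(f))
}

log_msg <- function(...) message("[habsuit] ", sprintf(...))

record_outputs <- function(out_dir, stage, cfg, files) {
  path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(path))
    jsonlite::read_json(path, simplifyVector = FALSE) else list()
  for (f in files)
    manifest[[f]] <- list(stage = stage, config_hash = config_hash(cfg))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

require_file <- function(path, what) {
  if (!file.exists(path))
    stop("missing input for this stage: ", what, " (", path, ")", call. = FALSE)
  path
}

load_factors <- function(cfg, out_dir) {
  if (!is.null(cfg$factors)) {
    paths <- cfg$factors
    out <- purrr::imap(paths, function(p, nm) read_ascii_grid(require_file(p, nm)))
    return(out)
  }
  files <- list.files(out_dir, pattern = "^factor_.*\\.asc$", full.names = TRUE)
  if (!length(files))
    stop("missing input for this stage: factor rasters (run the simulate stage ",
         "or set `factors` in the config)", call. = FALSE)
  out <- lapply(files, read_ascii_grid)
  names(out) <- sub("^factor_(.*)\\.asc$", "\\1", basename(files))
  out
}

load_points <- function(cfg, out_dir) {
  path <- if (!is.null(cfg$points)) cfg$points else file.path(out_dir, "points.csv")
  read_points(require_file(path, "sample points CSV"))
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic landscape, land cover, sample points with
#' contents), `sdm` (fit the distribution model, growth-suitability map,
#' AUC, contributions, response-curve optimal ranges), `fuzzy` (indicator
#' table, fitted memberships, standardized factor rasters), `overlay`
#' (objective weights, quality map, growth x quality production map,
#' land-cover mask), `classify` (three-class regionalization + area
#' statistics), `validate` (RMSE of the quality map against the
#' indicator), or `all` (every stage in order). Each stage writes its
#' artifacts into `out_dir` and records them in `manifest.json` together
#' with the MD5 hash of the configuration that produced them; progress
#' goes to standard error.
#'
#' @param stage stage name (see above).
#' @param config a config list ([read_pipeline_config()] /
#'   [default_config()]) or a path to a YAML config file.
#' @param out_dir output directory (created if needed).
#' @return The output directory, invisibly.
#' @export
run_stage <- function(stage = c("all", "simulate", "sdm", "fuzzy", "overlay",
                                "classify", "validate"),
                      config = default_config(), out_dir = ".") {
  stage <- match.arg(stage)
  cfg <- if (is.character(config)) read_pipeline_config(config)
         else utils::modifyList(default_config(), config)
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (stage == "all") {
    for (s in c("simulate", "sdm", "fuzzy", "overlay", "classify", "validate"))
      run_stage(s, cfg, out_dir)
    return(invisible(out_dir))
  }
  log_msg("stage %s (seed %d, config %s)", stage, cfg$seed, config_hash(cfg))

  switch(stage,
    simulate = stage_simulate(cfg, out_dir),
    sdm = stage_sdm(cfg, out_dir),
    fuzzy = stage_fuzzy(cfg, out_dir),
    overlay = stage_overlay(cfg, out_dir),
    classify = stage_classify(cfg, out_dir),
    validate = stage_validate(cfg, out_dir)
  )
  invisible(out_dir)
}

stage_simulate <- function(cfg, out_dir) {
  lc_cfg <- landscape_config(n_rows = cfg$n_rows, n_cols = cfg$n_cols,
                             cellsize = cfg$cellsize, seed = cfg$seed)
  truth <- ground_truth(noise_sd = cfg$noise_sd)
  factors <- generate_factor_rasters(lc_cfg)
  landcover <- generate_landcover(lc_cfg)
  suit <- simulate_true_suitability(factors, truth)
  pts <- sample_presence_points(suit, cfg$n_points, seed = split_seed(cfg$seed, 2001L))
  pts <- simulate_contents(pts, factors, truth, seed = split_seed(cfg$seed, 2002L))

  files <- character(0)
  for (nm in names(factors)) {
    f <- file.path(out_dir, sprintf("factor_%s.asc", nm))
    write_ascii_grid(factors[[nm]], f); files <- c(files, basename(f))
  }
  write_ascii_grid(landcover, file.path(out_dir, "landcover.asc"))
  write_ascii_grid(suit, file.path(out_dir, "true_suitability.asc"))
  write_points(pts, file.path(out_dir, "points.csv"))
  record_outputs(out_dir, "simulate", cfg,
                 c(files, "landcover.asc", "true_suitability.asc", "points.csv"))
}

stage_sdm <- function(cfg, out_dir) {
  factors <- load_factors(cfg, out_dir)
  pts <- load_points(cfg, out_dir)
  presence <- as.data.frame(lapply(factors, extract_at_points, points = pts))
  keep <- stats::complete.cases(presence)
  presence <- presence[keep, , drop = FALSE]
  set.seed(split_seed(cfg$seed, 3001L))
  tmpl <- factors[[1]]
  idx <- sample.int(n_cells(tmpl), size = min(cfg$n_background, n_cells(tmpl)))
  background <- as.data.frame(lapply(factors, function(r) as.vector(r$values)[idx]))
  background <- background[stats::complete.cases(background), , drop = FALSE]

  ev <- maxent_evaluate(presence, background, train_frac = cfg$train_frac,
                        seed = split_seed(cfg$seed, 3002L),
                        features = cfg$features, beta = cfg$beta)
  model <- fit_maxent(presence, background, features = cfg$features, beta = cfg$beta)
  contrib <- percent_contribution(model, presence, background,
                                  seed = split_seed(cfg$seed, 3003L))
  ranges <- purrr::map_dfr(model$variables, function(v) {
    rc <- response_curve(model, v)
    orng <- suppressWarnings(optimal_range(rc, fraction = cfg$fraction))
    tibble::tibble(variable = v, low = orng[["low"]], high = orng[["high"]])
  })
  growth <- predict(model, factors, type = "logistic")

  write_maxent(model, file.path(out_dir, "maxent_model.json"))
  write_ascii_grid(growth, file.path(out_dir, "growth_suitability.asc"))
  readr::write_csv(contrib, file.path(out_dir, "contributions.csv"), progress = FALSE)
  readr::write_csv(ranges, file.path(out_dir, "optimal_ranges.csv"), progress = FALSE)
  readr::write_csv(tibble::tibble(auc_train = ev$auc_train, auc_test = ev$auc_test),
                   file.path(out_dir, "model_evaluation.csv"), progress = FALSE)
  log_msg("sdm: AUC train %.3f / test %.3f", ev$auc_train, ev$auc_test)
  record_outputs(out_dir, "sdm", cfg,
                 c("maxent_model.json", "growth_suitability.asc",
                   "contributions.csv", "optimal_ranges.csv",
                   "model_evaluation.csv"))
}

stage_fuzzy <- function(cfg, out_dir) {
  factors <- load_factors(cfg, out_dir)
  pts <- load_points(cfg, out_dir)
  ind <- normalize_contents(pts)
  fits <- purrr::imap(factors, function(r, nm) {
    fit_membership(extract_at_points(r, pts), ind$indicator, family = cfg$family)
  })
  params_tbl <- purrr::imap_dfr(fits, function(f, nm) {
    p <- f$params
    tibble::tibble(factor = nm, family = p$family, a = p$a, b = p$b, c = p$c,
                   d = p$d, K = p$K, alpha = p$alpha, beta = p$beta,
                   rss = f$goodness, n_points = f$n_points)
  })
  files <- character(0)
  for (nm in names(factors)) {
    std <- standardize_raster(factors[[nm]], fits[[nm]]$params)
    f <- file.path(out_dir, sprintf("suitability_%s.asc", nm))
    write_ascii_grid(std, f); files <- c(files, basename(f))
  }
  readr::write_csv(ind, file.path(out_dir, "indicator.csv"), progress = FALSE)
  write_membership_params(params_tbl, file.path(out_dir, "membership_params.csv"))
  record_outputs(out_dir, "fuzzy", cfg,
                 c(files, "indicator.csv", "membership_params.csv"))
}

stage_overlay <- function(cfg, out_dir) {
  contrib <- readr::read_csv(require_file(file.path(out_dir, "contributions.csv"),
                                          "contribution table"),
                             show_col_types = FALSE, progress = FALSE)
  weights <- normalize_weights(contrib)
  std_files <- file.path(out_dir, sprintf("suitability_%s.asc", weights$variable))
  purrr::walk(std_files, require_file, what = "standardized factor raster")
  std <- stats::setNames(lapply(std_files, read_ascii_grid), weights$variable)
  quality <- weighted_overlay(std, weights)

  growth <- read_ascii_grid(require_file(file.path(out_dir, "growth_suitability.asc"),
                                         "growth suitability raster"))
  production <- combine_suitability(growth, quality, method = cfg$combine)
  lc_path <- if (!is.null(cfg$landcover)) cfg$landcover
             else file.path(out_dir, "landcover.asc")
  landcover <- read_ascii_grid(require_file(lc_path, "land-cover raster"))
  masked <- mask_landcover(production, landcover, cfg$allowed_classes)

  readr::write_csv(weights, file.path(out_dir, "weights.csv"), progress = FALSE)
  write_ascii_grid(quality, file.path(out_dir, "quality_suitability.asc"))
  write_ascii_grid(production, file.path(out_dir, "production_suitability.asc"))
  write_ascii_grid(masked, file.path(out_dir, "production_masked.asc"))
  record_outputs(out_dir, "overlay", cfg,
                 c("weights.csv", "quality_suitability.asc",
                   "production_suitability.asc", "production_masked.asc"))
}

stage_classify <- function(cfg, out_dir) {
  masked <- read_ascii_grid(require_file(file.path(out_dir, "production_masked.asc"),
                                         "masked production raster"))
  cl <- classify_suitability(masked, t_high = cfg$t_high, t_low = cfg$t_low)
  write_ascii_grid(cl$raster, file.path(out_dir, "classification.asc"))
  readr::write_csv(area_stats_report(cl), file.path(out_dir, "class_stats.csv"),
                   progress = FALSE)
  record_outputs(out_dir, "classify", cfg,
                 c("classification.asc", "class_stats.csv"))
}

stage_validate <- function(cfg, out_dir) {
  quality <- read_ascii_grid(require_file(file.path(out_dir, "quality_suitability.asc"),
                                          "quality suitability raster"))
  pts <- load_points(cfg, out_dir)
  ind <- readr::read_csv(require_file(file.path(out_dir, "indicator.csv"),
                                      "indicator table"),
                         show_col_types = FALSE, progress = FALSE)
  rep <- validate_map(quality, pts, ind)
  readr::write_csv(rep$points, file.path(out_dir, "validation.csv"), progress = FALSE)
  readr::write_csv(glance(rep), file.path(out_dir, "validation_summary.csv"),
                   progress = FALSE)
  log_msg("validate: RMSE %.4f over %d points", rep$rmse, rep$n_points)
  record_outputs(out_dir, "validate", cfg,
                 c("validation.csv", "validation_summary.csv"))
}
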