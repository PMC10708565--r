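# Workflow orchestration: the full crushed/full transfer-and-hybrid
# experiment in memory, and a file-based pipeline runner used by the CLI.
# Every stage seed derives from one master seed by a fixed offset, so a
# single seed reproduces a whole run.

#' Run the full transfer-and-hybrid experiment in memory
#'
#' Executes the complete workflow on a synthetic paired-form dataset (or a
#' supplied one): multiplicative scatter correction per form, CARS
#' wavelength screening per form and union of the two sets, a seeded 4:1
#' calibration/prediction split, epsilon-SVR models for both forms, SPXY/KS
#' standard-sample selection, direct standardization of the full-form
#' spectra into the crushed model's space, and hybrid-model sweeps.
#'
#' @param pair `NULL` to generate a fixture from `fixture_cfg`, or a list
#'   with `cs` and `fs` [spectral_dataset()] objects sharing ids.
#' @param fixture_cfg a [fixture_config()] used when `pair` is `NULL`.
#' @param seed master seed; stage seeds derive from it by fixed offsets.
#' @param svr an [svr_config()] for all epsilon-SVR fits.
#' @param cars list of CARS settings (`n_iterations`, `n_folds`, `mc_ratio`,
#'   `max_ncomp`).
#' @param standards list with `method` ("spxy"/"ks"), `scheme`, `n`.
#' @param svd_tol singular-value cutoff for the transfer.
#' @param k_grid hybrid added-sample counts.
#' @param hybrid_raw also sweep the untransferred hybrid (default TRUE).
#' @param cv compute cross-validation metrics for the per-form models.
#' @return list of class `transfer_experiment` with elements `split`,
#'   `selected_wavelengths`, `cs_model`, `metrics_cs` (crushed model on
#'   crushed samples), `metrics_fs_model` (full-form model on full-form
#'   samples), `metrics_fs_before` (crushed model fed the raw, untransferred
#'   full-form prediction spectra), `metrics_fs_after` (crushed model fed
#'   the DS-transferred spectra), `transfer`, `sweep_transferred`,
#'   `sweep_raw`, and the `datasets` used.
#' @export
transfer_experiment <- function(pair = NULL, fixture_cfg = fixture_config(),
                                seed = 1L, svr = svr_config(),
                                cars = list(n_iterations = 50L,
                                            n_folds = 10L, mc_ratio = 0.8,
                                            max_ncomp = 10L),
                                standards = list(method = "spxy",
                                                 scheme =
                                                   "crushed_as_standard",
                                                 n = 70L),
                                svd_tol = 1e-6,
                                k_grid = seq(5, 80, by = 5),
                                hybrid_raw = TRUE, cv = TRUE) {
  if (is.null(pair)) {
    fixture_cfg$seed <- derive_seed(seed, 1L)
    pair <- generate_dataset_pair(fixture_cfg)
  }
  cs <- pair$cs; fs <- pair$fs
  if (!identical(cs$spectra$sample_ids, fs$spectra$sample_ids)) {
    stop("alignment error: forms must share sample ids", call. = FALSE)
  }
  wl <- cs$spectra$wavelengths

  # 4:1 split shared by both forms
  split <- random_split(cs$spectra$sample_ids, seed = derive_seed(seed, 2L))
  attach_split <- function(ds) {
    spectral_dataset(ds$spectra, ds$y, split$calibration_ids,
                     split$prediction_ids)
  }
  cs <- attach_split(cs); fs <- attach_split(fs)

  # MSC per physical form, reference frozen on the calibration rows
  correct_form <- function(ds) {
    cal_idx <- match(split$calibration_ids, ds$spectra$sample_ids)
    model <- msc_fit(ds$spectra$X[cal_idx, , drop = FALSE])
    spectral_dataset(msc_apply(model, ds$spectra), ds$y,
                     split$calibration_ids, split$prediction_ids)
  }
  cs <- correct_form(cs); fs <- correct_form(fs)

  # CARS per form on the calibration rows, then the union rule
  run_cars <- function(ds, offset) {
    cal <- dataset_part(ds, "calibration")
    cars_run(cal$X, cal$y, n_iterations = cars$n_iterations,
             n_folds = cars$n_folds, mc_ratio = cars$mc_ratio,
             max_ncomp = cars$max_ncomp, seed = derive_seed(seed, offset),
             wavelengths = wl)
  }
  cars_cs <- run_cars(cs, 3L)
  cars_fs <- run_cars(fs, 4L)
  union_wl <- merge_variable_sets(cars_cs$selected_wavelengths,
                                  cars_fs$selected_wavelengths)
  bands <- map_wavelengths_to_bands(union_wl, wl)
  cs_v <- spectral_dataset(cs$spectra[, bands], cs$y,
                           split$calibration_ids, split$prediction_ids)
  fs_v <- spectral_dataset(fs$spectra[, bands], fs$y,
                           split$calibration_ids, split$prediction_ids)

  cs_cal <- dataset_part(cs_v, "calibration")
  cs_pred <- dataset_part(cs_v, "prediction")
  fs_cal <- dataset_part(fs_v, "calibration")
  fs_pred <- dataset_part(fs_v, "prediction")

  # per-form models on the union variable set
  fit_cs <- fit_and_evaluate(cs_cal$X, cs_cal$y, cs_pred$X, cs_pred$y,
                             config = svr, cv = cv,
                             seed = derive_seed(seed, 5L))
  fit_fs <- fit_and_evaluate(fs_cal$X, fs_cal$y, fs_pred$X, fs_pred$y,
                             config = svr, cv = cv,
                             seed = derive_seed(seed, 6L))

  # standard samples, DS transfer, crushed model applied to transferred FS
  n_std <- min(standards$n, length(split$calibration_ids))
  sel <- select_standards(cs_v, fs_v, scheme = standards$scheme,
                          method = standards$method, n = n_std)
  pairstd <- pair_standard_sets(sel, cs_v, fs_v, master = "crushed")
  tm <- compute_transfer(pairstd$master, pairstd$slave, svd_tol = svd_tol,
                         standard_ids = pairstd$ids)
  fs_pred_t <- apply_transfer(tm, fs_pred$X)
  yhat_cs_cal <- predict(fit_cs$model, cs_cal$X)
  # before transfer: the crushed model fed the raw full-form spectra
  metrics_before <- metrics_report(
    cs_cal$y, yhat_cs_cal,
    fs_pred$y, predict(fit_cs$model, fs_pred$X))
  metrics_after <- metrics_report(
    cs_cal$y, yhat_cs_cal,
    fs_pred$y, predict(fit_cs$model, fs_pred_t))

  # hybrid sweeps: crushed base plus k full-form calibration spectra
  fixed_svr <- svr_config(
    kernel = fit_cs$model$kernel, C = fit_cs$model$C,
    gamma = if (fit_cs$model$kernel == "rbf") fit_cs$model$gamma else NULL,
    epsilon = fit_cs$model$epsilon, tol = svr$tol,
    max_iter = svr$max_iter, scale = svr$scale)
  k_grid <- k_grid[k_grid <= nrow(fs_cal$X)]
  fs_cal_t <- apply_transfer(tm, fs_cal$X)
  sweep_t <- hybrid_sweep(cs_cal$X, cs_cal$y, fs_cal_t, fs_cal$y,
                          k_grid = k_grid, transferred = TRUE,
                          eval_X = fs_pred_t, eval_y = fs_pred$y,
                          config = fixed_svr, seed = derive_seed(seed, 7L))
  sweep_r <- NULL
  if (hybrid_raw) {
    sweep_r <- hybrid_sweep(cs_cal$X, cs_cal$y, fs_cal$X, fs_cal$y,
                            k_grid = k_grid, transferred = FALSE,
                            eval_X = fs_pred$X, eval_y = fs_pred$y,
                            config = fixed_svr,
                            seed = derive_seed(seed, 8L))
  }

  structure(list(split = split,
                 cars_cs = cars_cs, cars_fs = cars_fs,
                 selected_wavelengths = union_wl, bands = bands,
                 cs_model = fit_cs$model,
                 metrics_cs = fit_cs$metrics,
                 metrics_fs_model = fit_fs$metrics,
                 metrics_fs_before = metrics_before,
                 metrics_fs_after = metrics_after,
                 transfer = tm, standards = sel,
                 sweep_transferred = sweep_t, sweep_raw = sweep_r,
                 datasets = list(cs = cs_v, fs = fs_v),
                 seed = seed),
            class = "transfer_experiment")
}

#' @export
print.transfer_experiment <- function(x, ...) {
  cat("<transfer_experiment>\n")
  cat(sprintf("  union variable set: %d wavelengths\n",
              length(x$selected_wavelengths)))
  cat(sprintf("  full-form model on itself:     %.4f (RMSEP %.4f)\n",
              x$metrics_fs_model$Rp2, x$metrics_fs_model$RMSEP))
  cat(sprintf("  full-form Rp2 before transfer: %.4f (RMSEP %.4f)\n",
              x$metrics_fs_before$Rp2, x$metrics_fs_before$RMSEP))
  cat(sprintf("  full-form Rp2 after  transfer: %.4f (RMSEP %.4f)\n",
              x$metrics_fs_after$Rp2, x$metrics_fs_after$RMSEP))
  cat(sprintf("  best transferred hybrid: k = %d (RMSEP %.4f)\n",
              x$sweep_transferred$best_k,
              min(x$sweep_transferred$table$RMSEP)))
  invisible(x)
}

#' Pipeline configuration
#'
#' Stage blocks with the winning defaults: SPXY standard selection on the
#' crushed form, 70 standards, DS transfer into the crushed model's space,
#' and a 5-80 (step 5) transferred hybrid sweep. Unknown stage names or
#' stage keys are rejected.
#'
#' @param out_dir run directory for artifacts.
#' @param seed master seed (every stage seed derives from it).
#' @param io list: either `simulate = TRUE` (with optional `n_samples`) or
#'   paths `cs`, `fs` (spectra tables) and `tvc` (two-column id,value CSV).
#' @param cars,standards,transfer,model,hybrid,split stage parameter lists;
#'   see [transfer_experiment()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("spectransfer_run_"),
                            seed = 42L,
                            io = list(simulate = TRUE, n_samples = 100L),
                            split = list(ratio = c(4, 1)),
                            cars = list(n_iterations = 50L, n_folds = 10L,
                                        mc_ratio = 0.8, max_ncomp = 10L),
                            standards = list(method = "spxy",
                                             scheme = "crushed_as_standard",
                                             n = 70L),
                            transfer = list(svd_tol = 1e-6),
                            model = list(kernel = "rbf", C = NULL,
                                         gamma = NULL, epsilon = NULL,
                                         n_folds = 10L),
                            hybrid = list(k_grid = seq(5, 80, by = 5),
                                          raw = TRUE)) {
  check_keys <- function(block, allowed, name) {
    bad <- setdiff(names(block), allowed)
    if (length(bad)) stop("unknown key(s) in '", name, "': ",
                          paste(bad, collapse = ", "), call. = FALSE)
    block
  }
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed),
    io = check_keys(io, c("simulate", "n_samples", "cs", "fs", "tvc"), "io"),
    split = check_keys(split, "ratio", "split"),
    cars = check_keys(cars, c("n_iterations", "n_folds", "mc_ratio",
                              "max_ncomp"), "cars"),
    standards = check_keys(standards, c("method", "scheme", "n"),
                           "standards"),
    transfer = check_keys(transfer, "svd_tol", "transfer"),
    model = check_keys(model, c("kernel", "C", "gamma", "epsilon",
                                "n_folds", "C_grid", "gamma_grid",
                                "epsilon_grid"), "model"),
    hybrid = check_keys(hybrid, c("k_grid", "raw"), "hybrid"))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the file-based pipeline
#'
#' Loads or simulates the paired-form data, executes the whole workflow via
#' [transfer_experiment()] and writes every artifact (spectra tables,
#' selected variables, split, transfer model, metrics reports, hybrid sweep
#' tables and a log) into the run directory. Reruns with the same
#' configuration reproduce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return the run directory path, invisibly; the `transfer_experiment`
#'   result is attached as attribute `"experiment"`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "log.txt")
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  if (isTRUE(config$io$simulate)) {
    say("stage io: simulating %d paired samples (seed %d)",
        config$io$n_samples %||% 100L, config$seed)
    fcfg <- fixture_config(n_samples = config$io$n_samples %||% 100L,
                           seed = derive_seed(config$seed, 1L))
    pair <- generate_dataset_pair(fcfg)
  } else {
    say("stage io: reading %s / %s", config$io$cs, config$io$fs)
    tvc <- utils::read.csv(config$io$tvc, stringsAsFactors = FALSE)
    yv <- stats::setNames(as.numeric(tvc[[2L]]), as.character(tvc[[1L]]))
    pair <- list(
      cs = spectral_dataset(read_spectra_table(config$io$cs, "crushed"), yv),
      fs = spectral_dataset(read_spectra_table(config$io$fs, "full"), yv))
  }
  write_spectra_table(pair$cs$spectra, file.path(config$out_dir, "cs.csv"))
  write_spectra_table(pair$fs$spectra, file.path(config$out_dir, "fs.csv"))
  utils::write.csv(data.frame(sample_id = pair$cs$spectra$sample_ids,
                              log10_tvc = unname(pair$cs$y)),
                   file.path(config$out_dir, "tvc.csv"), row.names = FALSE)

  say("stages msc/cars/split/standards/transfer/model/hybrid: running")
  svr <- svr_config(kernel = config$model$kernel %||% "rbf",
                    C = config$model$C, gamma = config$model$gamma,
                    epsilon = config$model$epsilon,
                    n_folds = config$model$n_folds %||% 10L)
  for (g in c("C_grid", "gamma_grid", "epsilon_grid")) {
    if (!is.null(config$model[[g]])) svr[[g]] <- config$model[[g]]
  }
  ex <- transfer_experiment(pair = pair, seed = config$seed, svr = svr,
                             cars = config$cars,
                             standards = config$standards,
                             svd_tol = config$transfer$svd_tol %||% 1e-6,
                             k_grid = config$hybrid$k_grid,
                             hybrid_raw = isTRUE(config$hybrid$raw %||%
                                                   TRUE))

  jw <- function(x, f) jsonlite::write_json(
    x, file.path(config$out_dir, f), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  jw(list(calibration_ids = ex$split$calibration_ids,
          prediction_ids = ex$split$prediction_ids,
          seed = ex$split$seed), "split.json")
  jw(list(cs = ex$cars_cs$selected_wavelengths,
          fs = ex$cars_fs$selected_wavelengths,
          union = ex$selected_wavelengths,
          rmsecv_cs = ex$cars_cs$rmsecv_curve,
          rmsecv_fs = ex$cars_fs$rmsecv_curve,
          best_iteration_cs = ex$cars_cs$best_iteration,
          best_iteration_fs = ex$cars_fs$best_iteration), "vars.json")
  jw(list(standard_ids = ex$transfer$standard_ids,
          rank = ex$transfer$rank, svd_tol = ex$transfer$svd_tol,
          master_mean = ex$transfer$master_mean,
          slave_mean = ex$transfer$slave_mean,
          F = ex$transfer$F), "ds.json")
  jw(unclass(ex$metrics_fs_model), "metrics_fs_model.json")
  jw(unclass(ex$metrics_fs_before), "metrics_before_transfer.json")
  jw(unclass(ex$metrics_fs_after), "metrics_after_transfer.json")
  jw(unclass(ex$metrics_cs), "metrics_cs_model.json")
  utils::write.csv(ex$sweep_transferred$table,
                   file.path(config$out_dir, "hybrid_sweep_transferred.csv"),
                   row.names = FALSE)
  if (!is.null(ex$sweep_raw)) {
    utils::write.csv(ex$sweep_raw$table,
                     file.path(config$out_dir, "hybrid_sweep_raw.csv"),
                     row.names = FALSE)
  }
  fs_pred_ids <- ex$split$prediction_ids
  fs_pred_idx <- match(fs_pred_ids, ex$datasets$fs$spectra$sample_ids)
  transferred <- apply_transfer(
    ex$transfer, ex$datasets$fs$spectra$X[fs_pred_idx, , drop = FALSE])
  write_spectra_table(
    spectra_set(transferred, ex$datasets$fs$spectra$wavelengths,
                fs_pred_ids, "full"),
    file.path(config$out_dir, "fs_prediction_transferred.csv"))

  say("done: Rp2 before %.4f -> after %.4f; best hybrid k=%d RMSEP %.4f",
      ex$metrics_fs_before$Rp2, ex$metrics_fs_after$Rp2,
      ex$sweep_transferred$best_k, min(ex$sweep_transferred$table$RMSEP))
  writeLines(log_lines, logf)
  res <- structure(config$out_dir, experiment = ex)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
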