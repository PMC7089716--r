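#' Default end-to-end pipeline configuration
#'
#' A desk-scale demonstration configuration: a 64-pixel chest phantom, 5
#' energy channels, photon-starved acquisition, SART + LRTP
#' reconstruction with quality metrics, and a small lesion cohort pushed
#' through feature extraction and two-fold cross-validated
#' classification. Every stage derives its own seed from the global one.
#'
#' @param seed global seed.
#' @param out_dir artifact directory.
#' @export
default_pipeline_config <- function(seed = 1L, out_dir = tempfile("spectex_")) {
  list(
    seed = seed,
    out_dir = out_dir,
    stages = c("simulate", "project", "recon", "features", "classify"),
    simulate = list(side = 64L, energies_keV = c(35, 45, 55, 65, 75),
                    spacing_mm = 3,
                    n_benign = 6L, n_malignant = 6L),
    project = list(I0_total = 5e4, n_angles = 90L),
    recon = list(method = "lrtp", lambda_nuc = 3e3, beta_tp = 3000,
                 mu_penalty = 30, n_outer = 10L, inner_iters = 3L,
                 n_init_sart = 15L, sart_iters = 25L),
    features = list(levels = 16L, input = "descriptor", scheme = "raw"),
    classify = list(n_trees = 300L, n_runs = 5L)
  )
}

validate_pipeline_config <- function(config) {
  stages_all <- c("simulate", "project", "recon", "features", "classify")
  if (!all(config$stages %in% stages_all))
    stop("unknown stage(s): ",
         paste(setdiff(config$stages, stages_all), collapse = ", "),
         call. = FALSE)
  idx <- sort(match(config$stages, stages_all))
  if (!all(diff(idx) == 1))
    stop("stages must form a contiguous sub-chain of ",
         paste(stages_all, collapse = " -> "), call. = FALSE)
  if ("recon" %in% config$stages) {
    rc <- config$recon
    if (!rc$method %in% c("sart", "lrtp"))
      stop("recon$method must be 'sart' or 'lrtp'", call. = FALSE)
    if (rc$method == "lrtp" &&
        any(!c("lambda_nuc", "beta_tp", "mu_penalty") %in% names(rc)))
      stop("recon method 'lrtp' requires lambda_nuc, beta_tp and mu_penalty",
           call. = FALSE)
  }
  if ("project" %in% config$stages && config$project$I0_total <= 0)
    stop("project$I0_total must be positive", call. = FALSE)
  invisible(TRUE)
}

#' Run the simulation-to-classification pipeline
#'
#' Executes the configured contiguous sub-chain of
#' simulate -> project -> recon -> features -> classify, writing every
#' artifact under `config$out_dir` and returning a manifest. The whole
#' run is reproducible from `config$seed`.
#'
#' @param config see [default_pipeline_config()]; validated before any
#'   stage runs.
#' @return list: `manifest` (tibble of stage, artifact, path, seconds) and
#'   `results` (in-memory stage outputs).
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  manifest <- list()
  log_art <- function(stage, artifact, path, secs)
    manifest[[length(manifest) + 1]] <<-
      tibble::tibble(stage = stage, artifact = artifact,
                     path = path %||% NA_character_, seconds = secs)
  timed <- function(stage, code) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(code)
    list(out = out, secs = proc.time()[["elapsed"]] - t0)
  }

  if ("simulate" %in% config$stages) {
    sc <- config$simulate
    tm <- timed("simulate", {
      phantom <- make_chest_phantom(sc$side, seed = derive_seed(config$seed, "phantom"),
                                    spacing = sc$spacing_mm)
      truth <- synthesize_spectral(phantom, sc$energies_keV)
      cohort <- make_lesion_cohort(sc$n_benign, sc$n_malignant,
                                   seed = derive_seed(config$seed, "cohort"))
      list(phantom = phantom, truth = truth, cohort = cohort)
    })
    res$simulate <- tm$out
    p1 <- file.path(config$out_dir, "phantom.svtx")
    write_volume(tm$out$phantom, p1)
    p2 <- file.path(config$out_dir, "truth.svtx")
    write_volume(tm$out$truth, p2)
    p3 <- file.path(config$out_dir, "cohort.csv")
    write_cohort_manifest(tm$out$cohort, p3)
    log_art("simulate", "phantom", p1, tm$secs)
    log_art("simulate", "truth", p2, 0)
    log_art("simulate", "cohort_manifest", p3, 0)
  }

  if ("project" %in% config$stages) {
    pc <- config$project
    geom <- proj_geometry(config$simulate$side, n_angles = pc$n_angles)
    tm <- timed("project", project_spectral(
      res$simulate$truth, geom, I0_total = pc$I0_total,
      spacing_mm = config$simulate$spacing_mm,
      seed = derive_seed(config$seed, "project")))
    res$project <- list(sino = tm$out, geom = geom)
    log_art("project", "sinogram", NULL, tm$secs)
  }

  if ("recon" %in% config$stages) {
    rc <- config$recon
    tm <- timed("recon", {
      geom <- res$project$geom
      sino <- res$project$sino
      sart <- sart_reconstruct(sino, geom, n_iters = rc$sart_iters %||% 25L,
                               spacing_mm = config$simulate$spacing_mm)
      out <- list(sart = sart)
      if (rc$method == "lrtp") {
        masks <- masks_from_phantom(res$simulate$phantom)
        weights <- learn_mrf_weights(res$simulate$truth, masks)
        cfg <- recon_config(lambda_nuc = rc$lambda_nuc, beta_tp = rc$beta_tp,
                            mu_penalty = rc$mu_penalty,
                            n_outer = rc$n_outer %||% 10L,
                            inner_iters = rc$inner_iters %||% 3L,
                            n_init_sart = rc$n_init_sart %||% 15L,
                            seed = derive_seed(config$seed, "recon"))
        out$lrtp <- lrtp_reconstruct(sino, geom, weights, masks, cfg,
                                     spacing_mm = config$simulate$spacing_mm)
        out$quality <- rbind(
          cbind(method = "sart", image_quality(res$simulate$truth, sart)),
          cbind(method = "lrtp", image_quality(res$simulate$truth, out$lrtp$chi)))
      } else {
        out$quality <- cbind(method = "sart",
                             image_quality(res$simulate$truth, sart))
      }
      out
    })
    res$recon <- tm$out
    pq <- file.path(config$out_dir, "quality.csv")
    utils::write.csv(tm$out$quality, pq, row.names = FALSE)
    log_art("recon", "quality", pq, tm$secs)
  }

  if ("features" %in% config$stages) {
    fc <- config$features
    tm <- timed("features", cohort_features(
      res$simulate$cohort, config$simulate$energies_keV,
      input = fc$input %||% "descriptor", scheme = fc$scheme %||% "raw",
      levels = fc$levels %||% 16L,
      seed = derive_seed(config$seed, "features")))
    res$features <- tm$out
    pf <- file.path(config$out_dir, "features.csv")
    utils::write.csv(tm$out, pf, row.names = FALSE)
    log_art("features", "feature_table", pf, tm$secs)
  }

  if ("classify" %in% config$stages) {
    cc <- config$classify
    tm <- timed("classify", twofold_cv(
      res$features, classify_config(n_trees = cc$n_trees %||% 300L),
      n_runs = cc$n_runs %||% 5L,
      seed = derive_seed(config$seed, "classify")))
    res$classify <- tm$out
    pj <- file.path(config$out_dir, "cv_result.json")
    jsonlite::write_json(list(auc_mean = tm$out$auc_mean,
                              auc_std = tm$out$auc_std,
                              n_runs = tm$out$n_runs,
                              per_run_aucs = tm$out$per_run_aucs),
                         pj, auto_unbox = TRUE, digits = NA)
    log_art("classify", "cv_result", pj, tm$secs)
  }

  list(manifest = do.call(rbind, manifest), results = res)
}
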