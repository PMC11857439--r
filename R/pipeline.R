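#' Default end-to-end run configuration
#'
#' @param seed Global seed; per-stage seeds are derived from it by a fixed
#'   offset scheme (cohort +0, ROI noise +1e6, split +2e6, volumes +3e6,
#'   permutations +4e6) so any stage can be rerun in isolation.
#' @param outdir Results directory.
#' @param alpha FWE level for the voxel-wise stage, in (0, 1].
#' @param extent Cluster extent threshold (voxels).
#' @param n_perm Number of permutations (>= 100).
#' @param quantiles Centile levels for the normative stage.
#' @param regions Regions for the normative stage.
#' @param margins Cohort margins (see [cohort_margins()]).
#' @param roi_params Generator parameters (see [roi_generator_params()]).
#' @param volume_shape Grid for the synthetic volumes, or `NULL` to skip
#'   the volume/voxel-wise stages.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(seed = 1L, outdir = "results", alpha = 0.05,
                       extent = 50L, n_perm = 200L,
                       quantiles = c(0.01, 0.05, 0.25, 0.50, 0.75, 0.95,
                                     0.99),
                       regions = c("caudate_L", "caudate_R", "putamen_L",
                                   "putamen_R"),
                       margins = cohort_margins(),
                       roi_params = roi_generator_params(),
                       volume_shape = c(40L, 48L, 40L)) {
  cfg <- list(seed = seed, outdir = outdir, alpha = alpha, extent = extent,
              n_perm = n_perm, quantiles = quantiles, regions = regions,
              margins = margins, roi_params = roi_params,
              volume_shape = volume_shape)
  validate_run_config(cfg)
}

#' @rdname run_config
#' @param cfg A configuration list.
#' @export
validate_run_config <- function(cfg) {
  known <- c("seed", "outdir", "alpha", "extent", "n_perm", "quantiles",
             "regions", "margins", "roi_params", "volume_shape")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
    abort("config: `seed` must be a single integer")
  }
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha > 1) {
    abort("config: `alpha` must lie in (0, 1]")
  }
  if (cfg$n_perm < 100) abort("config: `n_perm` must be >= 100")
  if (cfg$extent < 1) abort("config: `extent` must be >= 1")
  if (any(cfg$quantiles <= 0 | cfg$quantiles >= 1)) {
    abort("config: `quantiles` must lie strictly in (0, 1)")
  }
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- run_config()
  for (k in names(raw)) defaults[[k]] <- raw[[k]]
  if ("volume_shape" %in% names(raw) && !is.null(raw$volume_shape)) {
    defaults$volume_shape <- as.integer(raw$volume_shape)
  }
  validate_run_config(unclass(defaults))
}

#' Run the full synthetic analysis pipeline
#'
#' Executes simulate, normalize, extract, ROI statistics, voxel-wise GLM
#' (when volumes are enabled) and the normative stage, writing CSV / NIfTI /
#' JSON outputs and a manifest (seeds, package version, md5 hashes of every
#' written file) into `cfg$outdir`. Identical configurations produce
#' byte-identical outputs.
#'
#' @param cfg A `run_config` (or plain list, validated on entry).
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(cfg = run_config()) {
  cfg <- validate_run_config(unclass(cfg))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(name) {
    p <- file.path(cfg$outdir, name)
    paths[[length(paths) + 1L]] <<- p
    p
  }

  cohort <- generate_cohort(margins = cfg$margins,
                            seed = derive_seed(cfg$seed, "cohort"))
  write.csv(cohort, emit("cohort.csv"), row.names = FALSE)

  roi_direct <- generate_roi_suv(cohort, params = cfg$roi_params,
                                 seed = derive_seed(cfg$seed, "roi"))

  voxel_outputs <- NULL
  if (!is.null(cfg$volume_shape)) {
    atlas <- generate_atlas(shape = cfg$volume_shape)
    write_atlas(atlas, emit("atlas.nii.gz"))
    paths[[length(paths) + 1L]] <- file.path(cfg$outdir, "atlas.labels.json")
    vparams <- volume_generator_params(shape = cfg$volume_shape)
    vols <- purrr::map(seq_len(nrow(cohort)), function(i) {
      generate_pet_volume(
        unlist(roi_direct[i, cfg$roi_params$region]), atlas, vparams,
        seed = derive_seed(cfg$seed, "volume", i)
      )
    })
    names(vols) <- cohort$subject_id
    nvols <- purrr::map(vols, intensity_normalize)
    roi_table <- extract_roi_table(nvols, atlas, normalize = FALSE,
                                   regions = cfg$regions)
    gm <- vapply(nvols, global_mean, numeric(1), atlas = atlas)
    design <- make_design(cohort, gm)
    mask <- atlas$labels > 0L
    smap <- fit_glm(nvols, design, mask)
    thr <- permutation_fwe(nvols, design, mask, n_perm = cfg$n_perm,
                           alpha = cfg$alpha,
                           seed = derive_seed(cfg$seed, "perm"))
    clusters <- cluster_table(smap, as.numeric(thr), extent = cfg$extent,
                              affine = atlas$affine)
    tmap <- pet_volume(ifelse(is.na(smap$t), 0, smap$t),
                       affine = atlas$affine, units = "normalized")
    write_pet_volume(tmap, emit("tmap.nii.gz"))
    jsonlite::write_json(
      list(threshold = as.numeric(thr), alpha = cfg$alpha,
           n_perm = cfg$n_perm, df = smap$df),
      emit("fwe_threshold.json"), auto_unbox = TRUE, digits = NA
    )
    write.csv(clusters, emit("clusters.csv"), row.names = FALSE)
    voxel_outputs <- list(threshold = as.numeric(thr), clusters = clusters)
  } else {
    roi_table <- roi_direct
  }
  write.csv(roi_table, emit("roi_table.csv"), row.names = FALSE)

  corr <- dplyr::bind_rows(
    pearson_age_correlation(roi_table, cohort, regions = cfg$regions),
    sex_stratified_correlation(roi_table, cohort, regions = cfg$regions)
  )
  write.csv(corr, emit("roi_correlations.csv"), row.names = FALSE)

  nrun <- run_normative(roi_table, cohort, regions = cfg$regions,
                        seed = derive_seed(cfg$seed, "split"),
                        quantiles = cfg$quantiles)
  write.csv(nrun$deviations, emit("deviations.csv"), row.names = FALSE)
  write.csv(nrun$centiles, emit("centile_curves.csv"), row.names = FALSE)
  write.csv(nrun$ev, emit("explained_variance.csv"), row.names = FALSE)
  jsonlite::write_json(
    purrr::map(nrun$models, function(m) {
      list(m_w = m$m_w, S_w = m$S_w, alpha = m$alpha, beta = m$beta,
           warp = as.list(m$warp), knots = m$basis$knots,
           age_range = m$basis$age_range, nlml = m$nlml)
    }),
    emit("normative_models.json"), digits = NA
  )

  manifest <- list(
    package = "striatnorm",
    version = as.character(utils::packageVersion("striatnorm")),
    seed = cfg$seed,
    stage_seeds = list(
      cohort = derive_seed(cfg$seed, "cohort"),
      roi = derive_seed(cfg$seed, "roi"),
      split = derive_seed(cfg$seed, "split"),
      perm = derive_seed(cfg$seed, "perm")
    ),
    alpha = cfg$alpha, extent = cfg$extent, n_perm = cfg$n_perm,
    files = as.list(setNames(
      unname(tools::md5sum(unlist(paths))), basename(unlist(paths))
    ))
  )
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
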