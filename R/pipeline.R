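#' Pipeline configuration
#'
#' All stage toggles and parameters of [run_pipeline()], with declared
#' defaults. The configuration serialises to YAML and reads back identically
#' (see [write_run_config()]), so a saved config plus the seed reproduces a
#' run exactly.
#'
#' @param seed Master seed for every stochastic stage.
#' @param stages Character vector of stages to run, a subset of
#'   `c("phantom", "preprocess", "biomarkers", "pathlines", "study",
#'   "repro")`.
#' @param phantom List: `omega_rad_s`, `mask_semiaxes_mm`, `venc_m_s`,
#'   `corrupt` (logical; apply [default_corruption()]).
#' @param preprocess List: `order`, `max_passes`, `denoise`.
#' @param biomarkers List: `stasis_threshold_m_s`, `peak_reduction`.
#' @param pathlines List: `dt_s` (`NULL`: frame duration / 5).
#' @param study List: `n_sr`, `n_af`, `within_cv` (named), `hr_effect`.
#' @param repro List: `biomarker`, `n_boot_ci`, `n_boot_dependent`.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = c("phantom", "preprocess", "biomarkers",
                                       "pathlines", "study", "repro"),
                            phantom = list(),
                            preprocess = list(),
                            biomarkers = list(),
                            pathlines = list(),
                            study = list(),
                            repro = list()) {
  merge_defaults <- function(user, def) {
    stopifnot(all(names(user) %in% names(def)))
    utils::modifyList(def, user)
  }
  cfg <- list(
    seed = as.integer(seed),
    stages = match.arg(stages, several.ok = TRUE,
                       choices = c("phantom", "preprocess", "biomarkers",
                                   "pathlines", "study", "repro")),
    phantom = merge_defaults(phantom, list(
      omega_rad_s = 28, mask_semiaxes_mm = c(28, 24, 20), venc_m_s = 1.2,
      corrupt = TRUE)),
    preprocess = merge_defaults(preprocess, list(
      order = 1L, max_passes = 3L, denoise = TRUE)),
    biomarkers = merge_defaults(biomarkers, list(
      stasis_threshold_m_s = 0.1, peak_reduction = "mean")),
    pathlines = merge_defaults(pathlines, list(dt_s = NULL)),
    study = merge_defaults(study, list(
      n_sr = 64L, n_af = 22L,
      within_cv = c(intra_obs = 0.03, inter_obs = 0.07, rescan = 0.10,
                    interval = 0.14),
      hr_effect = -0.005)),
    repro = merge_defaults(repro, list(
      biomarker = "stasis", n_boot_ci = 1000L, n_boot_dependent = 10000L)))
  class(cfg) <- "run_config"
  cfg
}

#' @rdname pipeline_config
#' @param cfg A `run_config`.
#' @param path YAML path.
#' @export
write_run_config <- function(cfg, path) {
  # named atomic vectors become YAML maps (names survive the round trip)
  listify <- function(x) {
    if (is.list(x)) lapply(x, listify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(listify(unclass(cfg)), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(seed = raw$seed, stages = unlist(raw$stages),
                  phantom = lapply(raw$phantom, simplify_yaml),
                  preprocess = lapply(raw$preprocess, simplify_yaml),
                  biomarkers = lapply(raw$biomarkers, simplify_yaml),
                  pathlines = lapply(raw$pathlines, simplify_yaml),
                  study = lapply(raw$study, simplify_yaml),
                  repro = lapply(raw$repro, simplify_yaml))
}

simplify_yaml <- function(x) {
  if (is.list(x) && length(x) && all(vapply(x, length, 1L) == 1) &&
      all(vapply(x, is.atomic, TRUE))) unlist(x) else x
}

#' Run the full phantom-to-statistics pipeline
#'
#' Executes the configured stages in order — phantom generation, velocity
#' corrections, biomarker extraction, pathline classification, study
#' simulation, reproducibility statistics — logging every stage's parameters,
#' and (optionally) writing the artifacts to `out_dir`: the input bundle
#' (`bundle/`), `biomarkers.json`, `pathlines.csv`, `measurements.csv`, and
#' `report.json`. Identical config + seed give identical outputs (the
#' `timestamp` field of the report aside). Inputs on disk are never
#' modified; all outputs go to `out_dir`.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return The report list, invisibly containing every stage's results.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  report <- list(
    config = unclass(cfg),
    package_version = as.character(utils::packageVersion("laflow4d")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  field <- mask <- truth <- static_mask <- NULL
  if ("phantom" %in% cfg$stages) {
    ph <- run_stage("phantom", {
      pc <- phantom_config(
        components = list(list(kind = "rigid_rotation",
                               omega_rad_s = cfg$phantom$omega_rad_s,
                               axis = c(0, 0, 1))),
        mask_semiaxes_mm = cfg$phantom$mask_semiaxes_mm,
        seed = cfg$seed)
      make_phantom(pc,
                   corruption = if (isTRUE(cfg$phantom$corrupt))
                     default_corruption() else NULL,
                   venc_m_s = cfg$phantom$venc_m_s)
    })
    field <- ph$field; mask <- ph$mask; truth <- ph$truth
    static_mask <- ph$static_mask
    report$phantom <- list(ground_truth = as.list(truth))
    if (!is.null(out_dir)) {
      write_flow_bundle(field, mask, file.path(out_dir, "bundle"))
    }
  }
  if ("preprocess" %in% cfg$stages && !is.null(field)) {
    pp <- run_stage("preprocess", {
      static <- static_mask %||% !mask$data
      preprocess_field(field, static, order = cfg$preprocess$order,
                       max_passes = cfg$preprocess$max_passes,
                       denoise = cfg$preprocess$denoise)
    })
    field <- pp$field
    report$preprocess <- list(
      eddy_coefficients = unname(as.list(as.data.frame(
        t(pp$eddy_fit$coefficients)))),
      residual_rms = pp$eddy_fit$residual_rms,
      log = field$log)
  }
  if ("biomarkers" %in% cfg$stages && !is.null(field)) {
    bm <- run_stage("biomarkers", {
      extract_biomarkers(field, mask,
                         stasis_threshold_m_s =
                           cfg$biomarkers$stasis_threshold_m_s,
                         peak_reduction = cfg$biomarkers$peak_reduction,
                         patterns = FALSE)
    })
    report$biomarkers <- as.list(bm)
    if (!is.null(out_dir)) {
      jsonlite::write_json(
        c(as.list(bm), list(provenance = list(
          seed = cfg$seed, package_version = report$package_version))),
        file.path(out_dir, "biomarkers.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  if ("pathlines" %in% cfg$stages && !is.null(field)) {
    pl <- run_stage("pathlines", {
      dt_s <- cfg$pathlines$dt_s %||% (field$grid$frame_duration_s / 5)
      integrate_pathlines(field, list(default_seed_plane(mask)),
                          dt_s = dt_s, mv_plane = default_mv_plane(mask))
    })
    report$pathlines <- list(
      n_pathlines = length(unique(pl$pathline_id)),
      pattern_systole = tryCatch(
        classify_flow_pattern(pl, "systole", field$grid, mask)$label,
        error = function(e) NA_character_),
      pattern_diastole = tryCatch(
        classify_flow_pattern(pl, "diastole", field$grid, mask)$label,
        error = function(e) NA_character_))
    if (!is.null(out_dir)) {
      write_pathlines_csv(pl, file.path(out_dir, "pathlines.csv"))
    }
  }
  tab <- NULL
  if ("study" %in% cfg$stages) {
    tab <- run_stage("study", {
      simulate_study(study_design(
        n_subjects = c(SR = cfg$study$n_sr, AF = cfg$study$n_af),
        within_cv = cfg$study$within_cv,
        hr_effect = cfg$study$hr_effect,
        seed = cfg$seed))
    })
    report$study <- list(n_rows = nrow(tab),
                         n_subjects = length(unique(tab$subject_id)))
    if (!is.null(out_dir)) {
      write_measurement_table(tab, file.path(out_dir, "measurements.csv"))
    }
  }
  if ("repro" %in% cfg$stages && !is.null(tab)) {
    rp <- run_stage("repro", {
      b <- cfg$repro$biomarker
      contrasts <- c("intra", "inter", "rescan", "interval")
      cells <- lapply(contrasts, function(ct) {
        pr <- cv_pairs(tab, b, ct)
        est <- within_subject_cv(pr, n_boot = cfg$repro$n_boot_ci,
                                 seed = cfg$seed)
        ba <- bland_altman(pr)
        list(cv = est$cv, ci_low = est$ci_low, ci_high = est$ci_high,
             bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
             n = est$n_subjects)
      })
      names(cells) <- contrasts
      pr_re <- cv_pairs(tab, b, "rescan")
      pr_iv <- cv_pairs(tab, b, "interval")
      common <- intersect(pr_re$subject_id, pr_iv$subject_id)
      cmp <- compare_cv_dependent(
        pr_re[pr_re$subject_id %in% common, ],
        pr_iv[pr_iv$subject_id %in% common, ],
        n_boot = cfg$repro$n_boot_dependent, seed = cfg$seed)
      list(biomarker = b, cells = cells,
           rescan_vs_interval = list(delta_cv = cmp$delta_cv,
                                     ci_low = cmp$ci_low,
                                     ci_high = cmp$ci_high,
                                     p_value = cmp$p_value,
                                     n_boot = cmp$n_boot))
    })
    report$repro <- rp
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_run_config(cfg, file.path(out_dir, "config.yaml"))
  }
  invisible(report)
}
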