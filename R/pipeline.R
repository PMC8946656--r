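#' End-to-end experiment runner
#'
#' Orchestrates simulate -> preprocess -> signatures -> classify / map /
#' stats from a single JSON (or list) run configuration. A single global
#' seed is fanned out to fixed per-stage child seeds (see [derive_seed()])
#' so partial reruns reproduce. Every artifact is written under
#' `output_dir` and referenced by the returned manifest; the summary
#' aggregates evaluation reports, boundary agreements and channel
#' statistics.
#'
#' @name pipeline_cli
NULL

stage_order <- c("simulate", "preprocess", "signatures", "classify",
                 "map", "stats")
stage_deps <- list(simulate = character(0), preprocess = "simulate",
                   signatures = "preprocess", classify = "signatures",
                   map = "signatures", stats = "signatures")

#' Validate a run configuration
#'
#' @param cfg list or path to a JSON config with fields `stages`, `seed`,
#'   `output_dir` and optional per-stage blocks (`simulate`, `preprocess`,
#'   `classify`, `map`, `stats`)
#' @return normalized config list
#' @export
validate_run_config <- function(cfg) {
  if (is.character(cfg)) cfg <- jsonlite::read_json(cfg, simplifyVector = TRUE)
  stages <- cfg$stages %||% stage_order
  bad <- setdiff(stages, stage_order)
  if (length(bad))
    afmi_stop("afmi_bad_config", "unknown stage(s): %s",
              paste(bad, collapse = ", "))
  for (s in stages) {
    need <- stage_deps[[s]]
    if (length(need) && !all(need %in% stages))
      afmi_stop("afmi_stage_dependency",
                "stage '%s' requires stage(s): %s", s,
                paste(setdiff(need, stages), collapse = ", "))
  }
  cfg$stages <- stage_order[stage_order %in% stages]
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  if (is.null(cfg$output_dir))
    afmi_stop("afmi_bad_config", "output_dir is required")
  cfg
}

spec_from_config <- function(cfg) {
  sim <- cfg$simulate %||% list()
  args <- sim[intersect(names(sim),
                        names(formals(phantom_spec)))]
  args$seed <- derive_seed(cfg$seed, "simulate")
  if (!is.null(args$image_shape)) args$image_shape <- unlist(args$image_shape)
  do.call(phantom_spec, args)
}

#' Run a configured experiment end to end
#'
#' @param cfg run configuration (list or JSON path); see
#'   [validate_run_config()]
#' @return run manifest: config hash, seed, artifact paths, summary
#' @export
run_experiment <- function(cfg) {
  cfg <- validate_run_config(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  art <- list()
  summary <- list(seed = cfg$seed)
  cfg_path <- file.path(cfg$output_dir, "run_config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  art$config <- cfg_path
  stage <- "validate"
  result <- tryCatch({
    spec <- spec_from_config(cfg)
    sig_tab <- NULL; rel <- NULL
    if ("signatures" %in% cfg$stages) {
      stage <- "signatures"
      pre_cfg <- if ("preprocess" %in% cfg$stages)
        do.call(preprocess_config,
                (cfg$preprocess %||% list())[
                  intersect(names(cfg$preprocess %||% list()),
                            names(formals(preprocess_config)))])
      else NULL
      sig_tab <- cohort_signature_table(spec, cfg = pre_cfg)
      rel <- relative_signatures(sig_tab,
                                 min_normal = cfg$min_normal %||% 10L)
      sig_path <- file.path(cfg$output_dir, "signatures.csv")
      write.csv(rel$table, sig_path, row.names = FALSE)
      art$signatures <- sig_path
      summary$n_sectors <- nrow(rel$table)
      summary$n_patients <- length(rel$references)
    }
    if ("classify" %in% cfg$stages) {
      stage <- "classify"
      cl <- cfg$classify %||% list()
      classes <- unlist(cl$classes %||% c("PTG", "OSSN"))
      rep <- cross_validate(
        rel$table[rel$table$label %in% afmi_classes(), ],
        mode = cl$cv %||% "kfold", k = cl$k %||% 10L,
        framework = cl$framework %||% "fused", classes = classes,
        seed = derive_seed(cfg$seed, "classify"))
      eval_path <- file.path(cfg$output_dir, "eval_report.json")
      jsonlite::write_json(unclass(rep), eval_path, auto_unbox = TRUE,
                           digits = NA, null = "null")
      art$eval_report <- eval_path
      summary$classification <- list(framework = rep$framework,
                                     task = paste(classes, collapse = "-vs-"),
                                     auc = rep$auc,
                                     accuracy_mean = rep$accuracy_mean)
    }
    if ("map" %in% cfg$stages) {
      stage <- "map"
      mp <- cfg$map %||% list()
      pat <- mp$patient %||% 1L
      st <- generate_patient(spec, pat)
      st$truth <- NULL
      if ("preprocess" %in% cfg$stages) st <- preprocess_stack(st)
      tab <- extract_signatures(st)
      ann <- select_annotations(tab, frac = mp$train_frac %||% 0.3,
                                min_per_class = mp$min_per_class %||% 20L,
                                seed = derive_seed(cfg$seed, "map"))
      bm <- detect_boundaries(st, ann, table = tab,
                              pca_k = mp$pca_k %||% 5L,
                              min_per_class = mp$min_per_class %||% 20L,
                              min_normal = cfg$min_normal %||% 10L,
                              base_channel = mp$base_channel %||% 10L)
      if (isTRUE(mp$smooth)) bm <- smooth_map(bm)
      grid_path <- file.path(cfg$output_dir, "boundary_grid.csv")
      write.table(bm$grid, grid_path, sep = ",", row.names = FALSE,
                  col.names = FALSE)
      ppm_path <- file.path(cfg$output_dir, "boundary_overlay.ppm")
      write_ppm(render_boundary_overlay(bm), ppm_path)
      art$boundary_grid <- grid_path
      art$boundary_overlay <- ppm_path
      summary$boundary <- list(patient = bm$patient_id,
                               agreement = bm$agreement)
    }
    if ("stats" %in% cfg$stages) {
      stage <- "stats"
      stt <- cfg$stats %||% list()
      cmp <- channel_comparison_table(
        rel$table, channels = unlist(stt$channels %||% c(3, 12, 30, 52)),
        per_patient = isTRUE(stt$per_patient))
      stats_path <- file.path(cfg$output_dir, "channel_stats.csv")
      write.csv(cmp, stats_path, row.names = FALSE)
      art$channel_stats <- stats_path
      summary$channel_stats <- lapply(seq_len(nrow(cmp)), function(i)
        list(channel = cmp$channel[i],
             pair = paste(cmp$group_a[i], cmp$group_b[i], sep = "-vs-"),
             p = cmp$p_value[i], stars = cmp$stars[i]))
    }
    TRUE
  }, error = function(e) {
    afmi_stop("afmi_stage_failed", "stage '%s' failed: %s", stage,
              conditionMessage(e))
  })
  summary_path <- file.path(cfg$output_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  art$summary <- summary_path
  manifest <- list(config_hash = unname(tools::md5sum(cfg_path)),
                   seed = cfg$seed, package_version =
                     as.character(utils::packageVersion("afmi")),
                   stages = cfg$stages, artifacts = art, summary = summary)
  manifest_path <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest$path <- manifest_path
  invisible(manifest)
}
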