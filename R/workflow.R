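#' Default pipeline configuration
#'
#' All tunables of every stage, with defaults reproducing the recipe
#' constants: STED GLCM distances {2,4,7,12,16} at angles {0, pi/2},
#' normalization quantiles (0.025, 0.995), Li threshold on a sigma = 16 px
#' blur, 512 px small-object/hole filters, erosion radius 3, 5 CV folds
#' and a 0.95 precision target.
#'
#' @return A nested `pipeline_config` list.
#' @export
default_pipeline_config <- function() {
  structure(list(
    profile = "sted",
    master_seed = 11L,
    synthesis = list(
      n_cells_per_condition = 100L,
      conditions = c("proliferating", "senescent"),
      treated_conditions = character(0),
      bad_fraction = 0.2,
      n_qc_train_per_class = 120L,
      shape = c(192L, 192L)
    ),
    detection = list(k_clusters = 2L, gaussian_sigma_px = 2,
                     erosion_radius_px = 3L),
    segmentation = list(q_low = 0.025, q_high = 0.995, blur_sigma_px = 16,
                        min_object_px = 512L, max_hole_px = 512L,
                        min_blur_contrast = 0.2, fill_holes_first = FALSE),
    glcm = list(distances = NULL, levels = 64L, pre_blur_sigma_px = 0.5),
    qc = list(target_precision = 0.95, n_folds = 5L, n_trees = 500L,
              threshold_override = NULL),
    models = list(svm_kernel = "radial", svm_cost = 1,
                  tsne_perplexity = 30),
    paths = list(out_dir = "results")
  ), class = "pipeline_config")
}

merge_config <- function(defaults, raw, path = "") {
  if (is.null(raw)) return(defaults)
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "))
  }
  for (k in names(raw)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], raw[[k]],
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- raw[[k]]
    }
  }
  defaults
}

#' Validate and complete a pipeline configuration
#'
#' Merges a raw configuration (a nested list, or the path of a YAML file)
#' over the defaults, rejecting unknown keys and enforcing cross-field
#' constraints (quantile ordering, positive distances, fraction ranges).
#'
#' @param raw nested list or YAML file path; `NULL` for pure defaults.
#' @return A validated `pipeline_config`.
#' @export
validate_config <- function(raw = NULL) {
  if (is.character(raw) && length(raw) == 1) raw <- yaml::read_yaml(raw)
  cfg <- merge_config(default_pipeline_config(), raw)
  with(cfg$segmentation, {
    if (!(q_low >= 0 && q_high <= 1 && q_low < q_high)) {
      stop("segmentation.q_low must be < segmentation.q_high within [0, 1]")
    }
  })
  if (!is.null(cfg$glcm$distances) && any(cfg$glcm$distances < 1)) {
    stop("glcm.distances must be positive integers")
  }
  if (cfg$synthesis$bad_fraction < 0 || cfg$synthesis$bad_fraction > 1) {
    stop("synthesis.bad_fraction must lie in [0, 1]")
  }
  if (cfg$qc$target_precision <= 0 || cfg$qc$target_precision > 1) {
    stop("qc.target_precision must lie in (0, 1]")
  }
  if (!cfg$profile %in% c("sted", "confocal")) {
    stop("profile must be 'sted' or 'confocal'")
  }
  structure(cfg, class = "pipeline_config")
}

config_glcm_params <- function(cfg) {
  glcm_params(cfg$profile, distances = cfg$glcm$distances,
              levels = cfg$glcm$levels,
              pre_blur_sigma_px = cfg$glcm$pre_blur_sigma_px,
              q_low = cfg$segmentation$q_low,
              q_high = cfg$segmentation$q_high)
}

config_seg_params <- function(cfg) {
  sted_seg_params(q_low = cfg$segmentation$q_low,
                  q_high = cfg$segmentation$q_high,
                  blur_sigma_px = cfg$segmentation$blur_sigma_px,
                  min_object_px = cfg$segmentation$min_object_px,
                  max_hole_px = cfg$segmentation$max_hole_px,
                  min_blur_contrast = cfg$segmentation$min_blur_contrast,
                  fill_holes_first = cfg$segmentation$fill_holes_first)
}

write_table_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Chains synthesis, segmentation, feature extraction, QC calibration and
#' filtering, t-SNE embedding, condition classification of treated
#' groups, and per-condition summaries, writing every intermediate table
#' under `config$paths$out_dir` and returning a run manifest. Identical
#' configuration and seed reproduce identical manifests and tables.
#'
#' @param config a [validate_config()] result (or raw list/YAML path).
#' @param write_outputs write CSV/JSON outputs under `paths$out_dir`.
#' @return A list with `manifest` plus all in-memory results (feature
#'   table, QC model and decisions, embedding, confusion summary,
#'   condition summaries).
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         write_outputs = TRUE) {
  cfg <- validate_config(unclass(config))
  seed <- cfg$master_seed
  syn <- cfg$synthesis
  gp <- config_glcm_params(cfg)
  sp <- config_seg_params(cfg)

  # 1. annotation set (labelled good/bad) for QC training
  qc_pop <- generate_population(syn$n_qc_train_per_class,
                                conditions = syn$conditions,
                                seed = split_seed(seed, 1),
                                bad_fraction = 1, shape = syn$shape)
  # 2. main population: reference conditions + treated groups
  all_conditions <- c(syn$conditions, syn$treated_conditions)
  pop <- generate_population(syn$n_cells_per_condition,
                             conditions = all_conditions,
                             seed = split_seed(seed, 2),
                             bad_fraction = syn$bad_fraction,
                             shape = syn$shape)

  # 3. segmentation + features
  qc_feat <- extract_features_table(qc_pop, cfg$profile, gp, sp)
  feat <- extract_features_table(pop, cfg$profile, gp, sp)

  # 4. QC: calibrate on the annotation set, filter the main population
  qc_model <- train_qc(qc_feat, qc_feat$qc_label,
                       target_precision = cfg$qc$target_precision,
                       n_folds = cfg$qc$n_folds, n_trees = cfg$qc$n_trees,
                       seed = split_seed(seed, 3))
  if (!is.null(cfg$qc$threshold_override)) {
    qc_model$threshold <- cfg$qc$threshold_override
  }
  decisions <- apply_qc(qc_model, feat)
  kept <- feat[decisions$keep, , drop = FALSE]

  # 5. embedding (reporting only)
  embedding <- NULL
  if (nrow(kept) > 3 * cfg$models$tsne_perplexity) {
    embedding <- embed_features(kept,
                                perplexity = cfg$models$tsne_perplexity,
                                seed = split_seed(seed, 4))
  }

  # 6. condition classifier on the kept reference cells
  ref <- kept$condition %in% syn$conditions
  confusion <- NULL
  cond_model <- NULL
  if (length(unique(kept$condition[ref])) >= 2) {
    cond_model <- train_condition(kept[ref, , drop = FALSE],
                                  kept$condition[ref],
                                  kernel = cfg$models$svm_kernel,
                                  cost = cfg$models$svm_cost,
                                  seed = split_seed(seed, 5))
    if (any(!ref)) {
      confusion <- classify_treated(cond_model, kept[!ref, , drop = FALSE],
                                    kept$condition[!ref])
    }
  }

  summaries <- condition_summaries(kept, kept$condition)

  manifest <- list(
    package_version = as.character(utils::packageVersion("senotex")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    master_seed = seed,
    config_hash = config_hash(cfg),
    qc_threshold = qc_model$threshold,
    counts = list(
      n_generated = length(pop),
      n_good_label = sum(vapply(pop, function(r) r$qc_label == "good", TRUE)),
      n_bad_label = sum(vapply(pop, function(r) r$qc_label == "bad", TRUE)),
      n_kept_qc = nrow(kept),
      n_classified = nrow(kept)
    )
  )

  if (write_outputs) {
    out <- cfg$paths$out_dir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_table_atomic(feat, file.path(out, "features.csv"))
    write_table_atomic(cbind(feat[, intersect("cell_id", colnames(feat)),
                                  drop = FALSE], decisions),
                       file.path(out, "qc_decisions.csv"))
    if (!is.null(embedding)) {
      write_table_atomic(data.frame(cell_id = kept$cell_id,
                                    condition = kept$condition,
                                    tsne1 = embedding$coords[, 1],
                                    tsne2 = embedding$coords[, 2]),
                         file.path(out, "embedding.csv"))
    }
    if (!is.null(confusion)) {
      write_table_atomic(confusion, file.path(out, "confusion.csv"))
    }
    write_table_atomic(summaries, file.path(out, "condition_summaries.csv"))
    tmp <- file.path(out, "manifest.json.tmp")
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    file.rename(tmp, file.path(out, "manifest.json"))
  }

  list(manifest = manifest, features = feat, qc_model = qc_model,
       qc_decisions = decisions, kept = kept, embedding = embedding,
       condition_model = cond_model, confusion = confusion,
       summaries = summaries)
}

# stable hash of the analytical configuration (output locations excluded)
# via its canonical JSON serialization
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$paths <- NULL
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(js, tmp)
  unname(tools::md5sum(tmp))
}
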